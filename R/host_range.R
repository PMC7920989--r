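#' Host-range tables
#'
#' A host-range table is an ordinary tibble whose first column, `bacterium`,
#' holds the strain labels and whose remaining columns hold one numeric lysis
#' profile per phage. Quantitative tables carry averaged cross-streak scores on
#' the 0--3 scale (0 = no infection, 3 = a fully or nearly fully degraded
#' bacterial lawn); binary tables hold 0/1 presence--absence of lysis. The
#' bacteria-on-rows, phages-on-columns orientation is used everywhere
#' internally; [read_host_range()] transposes on request.
#'
#' @name host_range
NULL

# ---- internal representation helpers ----------------------------------------

# tibble (bacterium + phage columns) -> numeric matrix with dimnames
hr_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"bacterium" %in% names(data)) {
    abort("host-range data must have a `bacterium` label column")
  }
  m <- as.matrix(data[setdiff(names(data), "bacterium")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(data$bacterium)
  m
}

hr_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  tibble(bacterium = rownames(m)) |> dplyr::bind_cols(out)
}

validate_host_range <- function(data, binary = FALSE,
                                arg = deparse(substitute(data))) {
  m <- hr_matrix(data)
  if (nrow(m) < 1L || ncol(m) < 1L) {
    abort(sprintf("`%s` must have at least one bacterium and one phage", arg))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("duplicate bacterium labels in `%s`: %s", arg,
                  paste(unique(rownames(m)[duplicated(rownames(m))]),
                        collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("duplicate phage labels in `%s`: %s", arg,
                  paste(unique(colnames(m)[duplicated(colnames(m))]),
                        collapse = ", ")))
  }
  if (anyNA(m)) abort(sprintf("`%s` contains missing values", arg))
  if (binary) {
    if (!all(m %in% c(0, 1))) {
      abort(sprintf("`%s` must be a binary 0/1 host-range table", arg))
    }
  } else if (any(m < 0 | m > 3)) {
    bad <- which(m < 0 | m > 3, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "lysis scores must lie in [0, 3]; got %g at bacterium '%s', phage '%s'",
      m[bad[1L], bad[2L]], rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
  }
  invisible(m)
}

# ---- i/o ---------------------------------------------------------------------

#' Read a host-range matrix from delimited text
#'
#' Reads a CSV or TSV file with one header row of column labels and a leading
#' column of row labels, and returns a quantitative host-range tibble in the
#' canonical bacteria-on-rows orientation (files stored phages-on-rows are
#' transposed on read). Scores are validated against the 0--3 cross-streak
#' scale.
#'
#' @param path path to a delimited text file.
#' @param orientation `"bacteria_rows"` (default) if rows are bacterial
#'   strains, `"phages_rows"` if rows are phages (the table is transposed).
#' @param delim field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` read as tab, anything else as comma).
#' @return a tibble with a `bacterium` column and one numeric column per phage.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(",phiA,phiB", "Ec1,0,1.5", "Ec2,3,0"), tf)
#' read_host_range(tf)
#' @export
read_host_range <- function(path,
                            orientation = c("bacteria_rows", "phages_rows"),
                            delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1L]][-1L]
  header <- trimws(gsub("^\"|\"$", "", header))
  if (anyDuplicated(header)) {
    abort(sprintf("duplicate phage label in header: %s",
                  paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  raw <- suppressWarnings(
    readr::read_delim(path, delim = delim,
                      col_types = readr::cols(.default = "c"),
                      na = character(), trim_ws = TRUE,
                      show_col_types = FALSE, progress = FALSE))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    abort(sprintf("malformed (ragged) input: row %d expected %s, got %s",
                  prob$row[1L], prob$expected[1L], prob$actual[1L]))
  }
  if (ncol(raw) < 2L) abort("input must have a label column and >= 1 data column")
  if (anyNA(raw)) abort("malformed (ragged) input: rows differ in field count")
  labels <- as.character(raw[[1L]])
  body <- as.matrix(raw[-1L])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                  body[bad[1L], bad[2L]], labels[bad[1L]],
                  colnames(body)[bad[2L]]))
  }
  dimnames(num) <- list(labels, colnames(body))
  if (orientation == "phages_rows") num <- t(num)
  out <- hr_tibble(num)
  validate_host_range(out)
  out
}

#' Write a host-range table to delimited text
#'
#' @param data a host-range tibble (quantitative or binary).
#' @param path output path; `.tsv` writes tab-separated, otherwise CSV
#'   (RFC 4180).
#' @return `path`, invisibly.
#' @export
write_host_range <- function(data, path) {
  hr_matrix(data) # validates shape/labels
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

# ---- binarize & fill ---------------------------------------------------------

#' Reduce a quantitative lytic spectrum to lytic / non-lytic
#'
#' A cell becomes 1 exactly when its averaged lysis score exceeds `threshold`.
#' The default threshold 0 treats any positive averaged score as lysis.
#'
#' @param data quantitative host-range tibble.
#' @param threshold lysis cutoff in `[0, 3)`; scores strictly greater become 1.
#' @return a binary host-range tibble.
#' @seealso [matrix_fill()] for the percentage of lytic interactions.
#' @export
binarize <- function(data, threshold = 0) {
  m <- validate_host_range(data)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 3) {
    abort("`threshold` must be a single number in [0, 3)")
  }
  b <- (m > threshold) * 1
  hr_tibble(b)
}

#' Fill of a host-range table
#'
#' The fill f is the percentage of cells that are successful infections:
#' `100 * ones / (rows * cols)` for a binary table; for a quantitative table
#' the cell counts as an infection when its score is positive.
#'
#' @param data host-range tibble.
#' @return fill as a percentage in `[0, 100]`.
#' @export
matrix_fill <- function(data) {
  m <- hr_matrix(data)
  100 * sum(m > 0) / length(m)
}

# ---- pruning -----------------------------------------------------------------

#' Remove empty and redundant all-presence lines
#'
#' Drops every all-zero row and column, and (by default) collapses duplicate
#' all-one rows, respectively columns, to a single representative -- the first
#' in input order. Empty and multiple fully filled lines carry no packing
#' information and would bias the temperature, so they are removed before
#' nestedness analysis; the fill is recomputed on the pruned table.
#'
#' @param data binary host-range tibble.
#' @param collapse_full collapse duplicate all-one rows/columns to one
#'   representative (default `TRUE`). The rule keeps one representative rather
#'   than deleting all full lines: a fully susceptible strain is still part of
#'   the network.
#' @return the pruned binary tibble, with a [prune_report()] attached as an
#'   attribute.
#' @export
prune_redundant <- function(data, collapse_full = TRUE) {
  m <- validate_host_range(data, binary = TRUE)
  rlab <- rownames(m); clab <- colnames(m)

  empty_r <- rlab[rowSums(m) == 0]
  empty_c <- clab[colSums(m) == 0]
  keep_r <- setdiff(rlab, empty_r)
  keep_c <- setdiff(clab, empty_c)
  if (length(keep_r) == 0L || length(keep_c) == 0L) {
    abort("pruning would empty the matrix (no non-empty rows or columns left)")
  }
  m2 <- m[keep_r, keep_c, drop = FALSE]

  coll_r <- character(); coll_c <- character()
  rep_r <- character(); rep_c <- character()
  if (isTRUE(collapse_full)) {
    full_r <- rownames(m2)[rowSums(m2) == ncol(m2)]
    if (length(full_r) > 1L) {
      rep_r <- full_r[1L]
      coll_r <- full_r[-1L]
      m2 <- m2[setdiff(rownames(m2), coll_r), , drop = FALSE]
    }
    full_c <- colnames(m2)[colSums(m2) == nrow(m2)]
    if (length(full_c) > 1L) {
      rep_c <- full_c[1L]
      coll_c <- full_c[-1L]
      m2 <- m2[, setdiff(colnames(m2), coll_c), drop = FALSE]
    }
  }

  out <- hr_tibble(m2)
  report <- list(
    removed_empty_rows = empty_r,
    removed_empty_cols = empty_c,
    collapsed_full_rows = coll_r,
    collapsed_full_cols = coll_c,
    representative_row = rep_r,
    representative_col = rep_c,
    fill = matrix_fill(out)
  )
  attr(out, "prune_report") <- report
  out
}

#' Retrieve the pruning report attached by [prune_redundant()]
#'
#' @param data a tibble returned by [prune_redundant()].
#' @return a list naming removed empty lines, collapsed full lines, the kept
#'   representatives, and the post-pruning fill.
#' @export
prune_report <- function(data) {
  attr(data, "prune_report")
}

# packing/temperature precondition: no empty lines, non-degenerate fill
check_packable <- function(m) {
  if (nrow(m) < 1L || ncol(m) < 1L) abort("matrix is empty")
  s <- sum(m)
  if (s == 0 || s == length(m)) {
    abort(paste0("degenerate fill (", 100 * s / length(m),
                 "%): temperature is undefined; prune the matrix first"))
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("matrix has empty rows or columns; apply prune_redundant() first")
  }
  invisible(m)
}
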