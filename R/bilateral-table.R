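#' Bilateral count tables
#'
#' A bilateral count table summarises paired-organ binary responses: for each
#' of `g` groups it records how many patients had 0, 1 or 2 responding organs.
#' Internally it is a 3 x g integer matrix with response counts `0`, `1`, `2`
#' as rows and groups as columns; group sizes `m_i` (column sums), response
#' totals `S_l` (row sums) and the grand total `N` are derived, never stored.
#'
#' @param x One of: a 3 x g matrix (rows = number of responding organs
#'   0, 1, 2; columns = groups); a data frame in the same wide layout,
#'   optionally with a leading `response` label column; or a numeric vector of
#'   length `3g` read group by group as `(m0, m1, m2)` (the flat, column-major
#'   layout).
#' @param group_labels Optional character vector of group names. Defaults to
#'   existing column names or `"g1" ... "gG"`.
#'
#' @return An object of class `bilateral_table`: an integer matrix with
#'   response rows `"0","1","2"` and one column per group.
#'
#' @examples
#' # the retinitis pigmentosa example: four genetic groups
#' rp <- bilateral_table(
#'   matrix(c(15, 6, 7, 7, 5, 9, 3, 2, 14, 67, 24, 57), nrow = 3),
#'   group_labels = c("DOM", "AR", "SL", "ISO")
#' )
#' rp
#' group_sizes(rp)
#' response_totals(rp)
#' @export
bilateral_table <- function(x, group_labels = NULL) {
  if (is.data.frame(x)) {
    first <- x[[1]]
    if (is.character(first) || is.factor(first) ||
        identical(names(x)[1], "response")) {
      x <- x[, -1, drop = FALSE]
    }
    if (is.null(group_labels)) group_labels <- names(x)
    x <- as.matrix(x)
  }
  if (is.matrix(x)) {
    if (nrow(x) != 3L) {
      stop("a bilateral table needs exactly 3 rows (0, 1, 2 responses), got ",
           nrow(x), call. = FALSE)
    }
    counts <- x
  } else if (is.numeric(x)) {
    if (length(x) %% 3L != 0L || length(x) == 0L) {
      stop("flat layout requires a vector of length 3g, got length ",
           length(x), call. = FALSE)
    }
    counts <- matrix(x, nrow = 3L)
  } else {
    stop("cannot interpret `x` as a bilateral count table", call. = FALSE)
  }
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage)) stop("counts contain missing or non-numeric cells",
                           call. = FALSE)
  if (any(storage < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(abs(storage - round(storage)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  counts <- matrix(as.integer(round(storage)), nrow = 3L,
                   ncol = ncol(counts))
  if (is.null(group_labels)) {
    group_labels <- colnames(x)
    if (is.null(group_labels)) group_labels <- paste0("g", seq_len(ncol(counts)))
  }
  if (length(group_labels) != ncol(counts)) {
    stop("group_labels has length ", length(group_labels), " but the table has ",
         ncol(counts), " groups", call. = FALSE)
  }
  dimnames(counts) <- list(response = c("0", "1", "2"), group = group_labels)
  structure(counts, class = c("bilateral_table", "matrix", "array"))
}

#' @rdname bilateral_table
#' @export
is_bilateral_table <- function(x) inherits(x, "bilateral_table")

#' @rdname bilateral_table
#' @export
as_bilateral_table <- function(x, group_labels = NULL) {
  if (is_bilateral_table(x)) return(x)
  bilateral_table(x, group_labels = group_labels)
}

#' Derived margins of a bilateral table
#'
#' @param table A [bilateral_table()] (or anything coercible to one).
#' @return `group_sizes()` returns the per-group patient counts `m_i`;
#'   `response_totals()` the totals `S_0, S_1, S_2` of patients with 0, 1, 2
#'   responding organs; `n_groups()` the number of groups.
#' @export
group_sizes <- function(table) {
  table <- as_bilateral_table(table)
  colSums(unclass(table))
}

#' @rdname group_sizes
#' @export
response_totals <- function(table) {
  table <- as_bilateral_table(table)
  rowSums(unclass(table))
}

#' @rdname group_sizes
#' @export
n_groups <- function(table) ncol(as_bilateral_table(table))

#' @export
print.bilateral_table <- function(x, ...) {
  m <- unclass(x)
  out <- cbind(m, Total = rowSums(m))
  out <- rbind(out, Total = colSums(out))
  cat("Bilateral count table:", ncol(m), "group(s),",
      sum(m), "patients\n")
  print(out)
  invisible(x)
}

#' @export
as.data.frame.bilateral_table <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Long-format view of a bilateral table
#'
#' @param x A `bilateral_table`.
#' @param ... Unused.
#' @return A tibble with columns `group`, `response` (0/1/2) and `count`.
#' @exportS3Method tibble::as_tibble
as_tibble.bilateral_table <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    group = rep(colnames(m), each = 3L),
    response = rep(0:2, times = ncol(m)),
    count = as.integer(m)
  )
}

# internal: validate a table for the homogeneity tests (g >= 2, no empty group)
check_testable <- function(table, min_groups = 2L) {
  table <- as_bilateral_table(table)
  if (n_groups(table) < min_groups) {
    stop("the homogeneity tests need at least ", min_groups,
         " groups, got ", n_groups(table), call. = FALSE)
  }
  if (any(group_sizes(table) < 1L)) {
    stop("every group must contain at least one patient", call. = FALSE)
  }
  table
}
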