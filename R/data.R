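#' Assemble a functional dataset from long-format tables
#'
#' Bundles N observed curves (sample paths), each evaluated on its own time
#' grid, together with an optional N x R matrix of scalar covariates. This is
#' the input container for all model fitting in the package.
#'
#' @param curves A data frame with columns `id`, `t`, `y`: one row per
#'   observed point. Rows may arrive in any order; they are grouped by `id`
#'   and sorted by `t` within curve. Duplicate `(id, t)` pairs are an error.
#' @param covariates Optional data frame with column `id` plus one numeric
#'   column per covariate, exactly one row per distinct curve id. `NULL` gives
#'   a covariate-free dataset (R = 0).
#'
#' @return An object of class `fmm_data`: a list with `curves` (tibble sorted
#'   by id then t), `ids`, `times`/`values` (per-curve lists), `n_i`, `N`,
#'   `X` (N x R numeric matrix, zero columns when R = 0) and `R`.
#' @export
#' @examples
#' d <- fmm_data(data.frame(id = rep(1:2, each = 3),
#'                          t = rep(c(0, .5, 1), 2),
#'                          y = rnorm(6)))
#' d$N; d$n_i
fmm_data <- function(curves, covariates = NULL) {
  curves <- as.data.frame(curves)
  need <- c("id", "t", "y")
  missing_cols <- setdiff(need, names(curves))
  if (length(missing_cols) > 0) {
    abort(paste0("Curve table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  for (col in c("t", "y")) {
    v <- curves[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      abort(sprintf("Column `%s` is not numeric (e.g. row %d).", col,
                    if (length(bad)) bad[1] else 1L))
    }
    if (any(!is.finite(v))) {
      abort(sprintf("Column `%s` has non-finite values (row %d).",
                    col, which(!is.finite(v))[1]))
    }
  }
  key <- paste(curves$id, curves$t, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    abort(sprintf(
      "Duplicate (id, t) pair at row %d (id = %s, t = %g). Aggregate or fix the table first.",
      dup, as.character(curves$id[dup]), curves$t[dup]))
  }
  ord <- order(as.character(curves$id), curves$t, method = "radix")
  curves <- curves[ord, need, drop = FALSE]
  ids <- unique(as.character(curves$id))
  sp <- split(seq_len(nrow(curves)), factor(as.character(curves$id), levels = ids))
  times <- lapply(sp, function(ix) curves$t[ix])
  values <- lapply(sp, function(ix) curves$y[ix])
  n_i <- vapply(times, length, integer(1))
  N <- length(ids)

  if (is.null(covariates)) {
    X <- matrix(numeric(0), nrow = N, ncol = 0)
    rownames(X) <- ids
  } else {
    covariates <- as.data.frame(covariates)
    if (!"id" %in% names(covariates)) abort("Covariate table is missing column `id`.")
    cov_ids <- as.character(covariates$id)
    if (anyDuplicated(cov_ids)) {
      abort(sprintf("Covariate table has duplicated id at row %d.",
                    which(duplicated(cov_ids))[1]))
    }
    miss <- setdiff(ids, cov_ids)
    extra <- setdiff(cov_ids, ids)
    if (length(miss) || length(extra)) {
      abort(paste0(
        "Curve/covariate id mismatch.",
        if (length(miss)) paste0(" Missing from covariates: ",
                                 paste(head(miss, 5), collapse = ", "), "."),
        if (length(extra)) paste0(" Unknown ids in covariates: ",
                                  paste(head(extra, 5), collapse = ", "), ".")))
    }
    xcols <- setdiff(names(covariates), "id")
    X <- as.matrix(covariates[match(ids, cov_ids), xcols, drop = FALSE])
    if (!is.numeric(X)) abort("Covariate columns must all be numeric.")
    if (any(!is.finite(X))) abort("Covariate values must be finite.")
    rownames(X) <- ids
    colnames(X) <- xcols
  }

  structure(
    list(curves = tibble::as_tibble(curves), ids = ids, times = times,
         values = values, n_i = n_i, N = N, X = X, R = ncol(X)),
    class = "fmm_data"
  )
}

#' @export
print.fmm_data <- function(x, ...) {
  cat(sprintf("<fmm_data> N = %d curves, n_i in [%d, %d], R = %d covariate(s)\n",
              x$N, min(x$n_i), max(x$n_i), x$R))
  invisible(x)
}

#' Read a functional dataset from delimited files
#'
#' Reads a long-format curve table (`id,t,y`) and an optional covariate table
#' (`id,<name1>,...`) from CSV or TSV files (delimiter guessed from the
#' extension, comma by default) and assembles an [fmm_data()] object.
#'
#' @param curve_path Path to the curve table.
#' @param covariate_path Optional path to the covariate table.
#' @return An `fmm_data` object.
#' @export
read_fmm_data <- function(curve_path, covariate_path = NULL) {
  read_one <- function(path) {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    # parse numeric columns through strtod (correctly rounded) rather than
    # the reader's fast path, so written doubles roundtrip bitwise
    tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
    for (nm in setdiff(names(tb), "id")) {
      num <- suppressWarnings(as.numeric(tb[[nm]]))
      if (any(is.na(num) & !is.na(tb[[nm]]))) {
        bad <- which(is.na(num) & !is.na(tb[[nm]]))[1]
        abort(sprintf("Column `%s` of %s is not numeric (row %d: \"%s\").",
                      nm, path, bad, tb[[nm]][bad]))
      }
      tb[[nm]] <- num
    }
    tb
  }
  curves <- read_one(curve_path)
  covariates <- if (!is.null(covariate_path)) read_one(covariate_path)
  fmm_data(curves, covariates)
}

#' Write a functional dataset to delimited files
#'
#' Inverse of [read_fmm_data()]: writes the long curve table and, when R > 0,
#' the covariate table as CSV.
#'
#' @param data An `fmm_data` object.
#' @param curve_path Output path for the curve table.
#' @param covariate_path Output path for the covariate table (required when
#'   the dataset has covariates).
#' @return Invisibly, `data`.
#' @export
write_fmm_data <- function(data, curve_path, covariate_path = NULL) {
  stopifnot(inherits(data, "fmm_data"))
  # 17 significant digits guarantee a bitwise double roundtrip through text
  fmt <- function(df) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
    df
  }
  readr::write_csv(fmt(data$curves), curve_path, progress = FALSE)
  if (data$R > 0) {
    if (is.null(covariate_path)) {
      abort("Dataset has covariates; supply `covariate_path`.")
    }
    covs <- tibble::as_tibble(as.data.frame(data$X))
    covs <- dplyr::bind_cols(tibble(id = data$ids), covs)
    readr::write_csv(fmt(covs), covariate_path, progress = FALSE)
  }
  invisible(data)
}

#' Standardize a covariate matrix
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (the n-1 convention). Standardized covariates make the
#' population-level feature means interpretable as the mean at the average
#' covariate value, and are assumed by the identifiability conditions (the
#' all-ones vector must not lie in the column space of the design). The
#' centers and scales are recorded so fitted effects can be mapped back to
#' raw units.
#'
#' @param X_raw Numeric matrix (N x R) or data frame of raw covariates.
#' @return An object of class `fmm_design`: list with `X_std`, `centers`,
#'   `scales`, `R`.
#' @export
#' @examples
#' standardize_covariates(cbind(age = c(1, 2, 3)))$X_std
standardize_covariates <- function(X_raw) {
  X <- as.matrix(X_raw)
  if (!is.numeric(X)) abort("Covariates must be numeric.")
  N <- nrow(X); R <- ncol(X)
  if (R > 0 && N < 2) abort("Need at least two rows to standardize covariates.")
  centers <- numeric(R); scales <- numeric(R)
  X_std <- X
  for (r in seq_len(R)) {
    s <- sd(X[, r])
    if (!is.finite(s) || s == 0) {
      nm <- colnames(X)[r]
      abort(sprintf(
        "Covariate column %s is constant; it cannot be standardized (and would put the intercept in the design span).",
        if (is.null(nm) || nm == "") as.character(r) else sprintf("`%s`", nm)))
    }
    centers[r] <- mean(X[, r]); scales[r] <- s
    X_std[, r] <- (X[, r] - centers[r]) / scales[r]
  }
  names(centers) <- colnames(X); names(scales) <- colnames(X)
  structure(list(X_std = X_std, centers = centers, scales = scales, R = R),
            class = "fmm_design")
}

rank_svd <- function(A, rel_tol = 1e-8) {
  if (length(A) == 0 || min(dim(A)) == 0) return(0L)
  s <- svd(A, nu = 0, nv = 0)$d
  sum(s > rel_tol * s[1])
}

#' Validate a functional dataset against the model's identifiability checks
#'
#' Runs the checkable identifiability conditions for the covariate-adjusted
#' mixed membership model: the standardized design has full column rank and
#' does not contain the intercept in its span; every curve has more observed
#' points than basis functions (`n_i > P`); and time grids are regular
#' (irregular grids draw a warning entry rather than a failure, since the
#' identifiability result is stated for regularly sampled paths).
#'
#' @param data An [fmm_data()] object.
#' @param design Optional [standardize_covariates()] result; defaults to the
#'   standardization of `data$X` (skipped when R = 0).
#' @param P Basis dimension the model will use.
#' @return A tibble with columns `check`, `status` (`"pass"`, `"fail"` or
#'   `"warn"`) and `detail`; attribute `ok` is `TRUE` when nothing failed.
#' @export
validate_fmm_data <- function(data, design = NULL, P) {
  stopifnot(inherits(data, "fmm_data"))
  P <- as.integer(P)
  rows <- list()
  add <- function(check, status, detail) {
    rows[[length(rows) + 1L]] <<- tibble(check = check, status = status,
                                         detail = detail)
  }

  increasing <- vapply(data$times, function(t) all(diff(t) > 0), logical(1))
  add("times strictly increasing within curve",
      if (all(increasing)) "pass" else "fail",
      if (all(increasing)) "" else paste0("curves: ",
        paste(head(data$ids[!increasing], 5), collapse = ", ")))

  if (data$R > 0) {
    if (is.null(design)) design <- standardize_covariates(data$X)
    X <- design$X_std
    r1 <- rank_svd(X)
    add("design has full column rank", if (r1 == ncol(X)) "pass" else "fail",
        sprintf("rank %d of %d", r1, ncol(X)))
    r2 <- rank_svd(cbind(1, X))
    add("intercept not in design span", if (r2 == ncol(X) + 1L) "pass" else "fail",
        if (r2 == ncol(X) + 1L) "" else "the all-ones vector lies in the span of the covariates")
  } else {
    add("design has full column rank", "pass", "R = 0, nothing to check")
    add("intercept not in design span", "pass", "R = 0, nothing to check")
  }

  enough <- data$n_i > P
  add(sprintf("every curve has n_i > P (P = %d)", P),
      if (all(enough)) "pass" else "fail",
      if (all(enough)) "" else sprintf("%d curve(s) with n_i <= P (e.g. id %s, n_i = %d)",
        sum(!enough), data$ids[which(!enough)[1]], data$n_i[which(!enough)[1]]))

  regular <- vapply(data$times, function(t) {
    length(t) < 3L || {
      d <- diff(t); diff(range(d)) <= 1e-8 * max(abs(d))
    }
  }, logical(1))
  add("time grids regular",
      if (all(regular)) "pass" else "warn",
      if (all(regular)) "" else
        "identifiability is established for regularly sampled paths; irregular grids are used as-is")

  out <- dplyr::bind_rows(rows)
  attr(out, "ok") <- !any(out$status == "fail")
  out
}
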