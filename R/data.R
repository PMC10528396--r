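#' Bundle a design and response for Bayesian variable selection
#'
#' Collects the selectable covariate matrix `x`, an optional always-included
#' matrix `z`, and the response into a single immutable object that every
#' sampler and marginal-likelihood engine consumes. For `family = "logistic"`
#' the response is a 0/1 vector `y`; for the survival families it is a pair of
#' observed times and right-censoring indicators (`time`, `event`), with
#' `event = 1` marking an observed event and `event = 0` a censored follow-up.
#'
#' @param x numeric matrix, n x p, covariates subject to selection.
#' @param y binary response vector (logistic family only).
#' @param time positive observed times (survival families).
#' @param event 0/1 event indicators (survival families).
#' @param z optional numeric matrix, n x q, of covariates forced into every
#'   model (e.g. an intercept column, clinical adjustments). May be `NULL`.
#' @param family one of `"logistic"`, `"cox"` (partial likelihood) or
#'   `"weibull"`.
#' @param shape initial Weibull shape parameter k (ignored otherwise).
#'
#' @return An object of class `"bvs_data"`: a list with elements `x`, `z`,
#'   `y` or (`time`, `event`), `family`, `n`, `p`, `q` and, for the Cox
#'   family, precomputed risk-set bookkeeping.
#' @export
bvs_data <- function(x, y = NULL, time = NULL, event = NULL, z = NULL,
                     family = c("logistic", "cox", "weibull"), shape = 1) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(n >= 1L, all(is.finite(x)))
  if (is.null(z)) {
    z <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    z <- as.matrix(z)
    storage.mode(z) <- "double"
    stopifnot(nrow(z) == n, all(is.finite(z)))
  }
  obj <- list(x = x, z = z, family = family, n = n, p = p, q = ncol(z))
  if (family == "logistic") {
    stopifnot(!is.null(y))
    y <- as.numeric(y)
    stopifnot(length(y) == n, all(y %in% c(0, 1)))
    obj$y <- y
  } else {
    stopifnot(!is.null(time), !is.null(event))
    time <- as.numeric(time)
    event <- as.numeric(event)
    stopifnot(length(time) == n, length(event) == n,
              all(time > 0), all(event %in% c(0, 1)))
    obj$time <- time
    obj$event <- event
    if (family == "cox") {
      # Risk sets R(t) = {i : t_i >= t}, assembled once from the ascending
      # time order; ties are handled with the Breslow convention.
      ord <- order(time)
      obj$cox_ord <- ord
      obj$cox_event_pos <- which(event[ord] == 1)  # event positions, time order
    } else {
      obj$shape <- shape
      obj$log_time <- log(time)
    }
  }
  class(obj) <- "bvs_data"
  obj
}

#' @export
print.bvs_data <- function(x, ...) {
  cat(sprintf("bvs_data: family=%s, n=%d, p=%d selectable, q=%d fixed\n",
              x$family, x$n, x$p, x$q))
  if (x$family != "logistic")
    cat(sprintf("  events: %d / %d (censoring %.1f%%)\n", sum(x$event), x$n,
                100 * mean(x$event == 0)))
  invisible(x)
}

#' Read a delimited data set for variable selection
#'
#' Expects a header row. The response columns are `y` (logistic) or
#' `time` + `event` (survival); columns named in `fixed` become the
#' always-included matrix Z and every remaining column enters X.
#'
#' @param file path to a CSV/TSV file.
#' @param family model family, as in [bvs_data()].
#' @param fixed character vector of column names forced into every model.
#' @param sep field separator, inferred from the extension by default.
#' @return A [bvs_data()] object; covariate names are preserved.
#' @export
read_bvs_data <- function(file, family = c("logistic", "cox", "weibull"),
                          fixed = character(), sep = NULL) {
  family <- match.arg(family)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  resp_cols <- if (family == "logistic") "y" else c("time", "event")
  if (!all(resp_cols %in% names(df)))
    stop("response column(s) ", paste(resp_cols, collapse = ", "),
         " not found in ", file)
  covars <- setdiff(names(df), c(resp_cols, fixed))
  x <- as.matrix(df[, covars, drop = FALSE])
  z <- if (length(fixed)) as.matrix(df[, fixed, drop = FALSE]) else NULL
  if (family == "logistic") {
    bvs_data(x, y = df$y, z = z, family = family)
  } else {
    bvs_data(x, time = df$time, event = df$event, z = z, family = family)
  }
}

#' Design matrix of a model
#'
#' Builds J_gamma = (Z, X_gamma): the fixed covariates first, then the
#' selected columns of X in ascending index order.
#'
#' @param gamma integer vector of selected column indices (sorted or not) or
#'   a logical/0-1 vector of length p.
#' @param data a [bvs_data()] object.
#' @return numeric matrix n x (q + p_gamma).
#' @export
build_design <- function(gamma, data) {
  idx <- gamma_index(gamma, data$p)
  cbind(data$z, data$x[, idx, drop = FALSE])
}

# Normalise a model indicator to a sorted integer index vector. Accepts a
# logical length-p vector, a 0/1 length-p vector (p >= 2, or containing a 0),
# or an integer vector of selected column indices.
gamma_index <- function(gamma, p) {
  if (is.logical(gamma)) {
    stopifnot(length(gamma) == p)
    return(which(gamma))
  }
  gamma <- as.integer(gamma)
  binary <- length(gamma) == p && all(gamma %in% c(0L, 1L)) &&
    (p >= 2L || any(gamma == 0L))
  if (binary) return(which(gamma == 1L))
  if (length(gamma) && (min(gamma) < 1L || max(gamma) > p))
    stop("model indicator refers to columns outside 1..p")
  sort(unique(gamma))
}

# Compact string key for a model, used by engine caches.
gamma_key <- function(idx) {
  if (!length(idx)) "{}" else paste(idx, collapse = ",")
}
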