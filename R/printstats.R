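#' Pairwise regression between ink properties
#'
#' Ordinary least squares between two per-ink quantities on declared axis
#' transforms; the correlation coefficient r^2 is the squared Pearson
#' correlation of the transformed data.  Decade-spanning quantities (`g0`,
#' `sigma_y`, `gamma_cr1`, `gamma_cr2`, `print_force`) default to log10
#' axes, bounded ones (`tan_delta`, `n1`, `n2`, `dev`) to identity; pass
#' `transform` to override.
#'
#' @param records an [ink_records()] table.
#' @param x,y column names.
#' @param transform named character vector `c(x = ..., y = ...)` with values
#'   `"identity"` or `"log10"`; `NULL` picks the field defaults above.
#' @param subset an ink class label, or `NULL` for the pooled set.
#' @return An object of class `ink_regression`: `slope`, `intercept`, `r2`,
#'   `n`, `transform`, `subset`, `x`, `y`.
#' @export
pairwise_regression <- function(records, x, y, transform = NULL,
                                subset = NULL) {
  stopifnot(inherits(records, "ink_records"))
  for (v in c(x, y)) if (is.null(records[[v]]))
    stop("no such column: ", v)
  df <- as.data.frame(records)
  if (!is.null(subset)) df <- df[df$ink_class == subset, , drop = FALSE]
  df <- df[stats::complete.cases(df[, c(x, y)]), , drop = FALSE]
  if (nrow(df) < 3)
    stop(sprintf("insufficient records for %s ~ %s (%s): %d usable",
                 y, x, subset %||% "pooled", nrow(df)))
  transform <- transform %||% c(x = .default_transform(x),
                                y = .default_transform(y))
  tx <- .apply_transform(df[[x]], transform[["x"]], x, df$ink_id)
  ty <- .apply_transform(df[[y]], transform[["y"]], y, df$ink_id)
  if (stats::sd(tx) == 0 || stats::sd(ty) == 0)
    stop(sprintf("zero variance in %s ~ %s (%s)", y, x,
                 subset %||% "pooled"))
  fit <- stats::lm(ty ~ tx)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = stats::cor(tx, ty)^2,
                 n = nrow(df), transform = transform,
                 subset = subset %||% "pooled", x = x, y = y),
            class = "ink_regression")
}

.default_transform <- function(field) {
  if (field %in% c("g0", "sigma_y", "gamma_cr1", "gamma_cr2", "print_force"))
    "log10" else "identity"
}

.apply_transform <- function(v, tr, field, ids) {
  switch(tr,
         identity = v,
         log10 = {
           bad <- v <= 0
           if (any(bad))
             stop(sprintf("log10 transform of %s: non-positive values for %s",
                          field, paste(ids[bad], collapse = ", ")))
           log10(v)
         },
         stop("unknown transform: ", tr))
}

#' @export
print.ink_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s]: slope = %.4g, r2 = %.3f (n = %d, %s/%s axes)\n",
              x$y, x$x, x$subset, x$slope, x$r2, x$n,
              x$transform[["x"]], x$transform[["y"]]))
  invisible(x)
}

#' Collapse per-class critical strains onto a master curve
#'
#' Across ink classes the deviation metric follows a common trend in the
#' critical strain, but displaced horizontally per class.  This finds
#' positive per-class scales \eqn{s_c} (the reference class fixed at 1)
#' minimizing the summed squared vertical residuals of `dev` around a
#' single monotone (non-increasing) trend fitted to the pooled
#' `(log10(gamma_cr1 / s_c), dev)` points.  The trend is an isotonic
#' (pool-adjacent-violators) fit; the scale offsets are found by an
#' exhaustive log-scale grid search refined by Nelder-Mead, so the result
#' is deterministic.
#'
#' The absolute characteristic strain of class c is reported as
#' `gamma_char[c] = s_c * g_ref` with `g_ref` the geometric mean
#' `gamma_cr1` of the reference class (the reference keeps its raw scale).
#'
#' @param records an [ink_records()] table with `gamma_cr1` and `dev`.
#' @param reference_class class fixed at unit scale (default carbohydrate).
#' @param grid log10 offsets searched for each non-reference class.
#' @return An object of class `collapse_result`: `scales` (named, reference
#'   = 1), `gamma_char`, `objective` (RSS at the optimum), `trend`
#'   (data.frame of rescaled log-strain and fitted dev), `classes_used`.
#' @export
collapse_gamma_cr <- function(records, reference_class = "carbohydrate",
                              grid = seq(-2, 2, by = 0.05)) {
  stopifnot(inherits(records, "ink_records"))
  df <- as.data.frame(records)
  df <- df[stats::complete.cases(df[, c("gamma_cr1", "dev")]), , drop = FALSE]
  counts <- table(df$ink_class)
  keep <- names(counts)[counts >= 3]
  drop <- setdiff(names(counts), keep)
  if (length(drop) > 0)
    warning("class(es) with < 3 usable records excluded: ",
            paste(drop, collapse = ", "))
  df <- df[df$ink_class %in% keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no usable records")
  if (!(reference_class %in% keep)) {
    reference_class <- keep[1]
    warning("reference class unusable; using ", reference_class)
  }
  free <- setdiff(keep, reference_class)
  lg <- log10(df$gamma_cr1)
  cls <- df$ink_class
  dev <- df$dev

  rss <- function(offsets) {   # named log10 scale offsets for free classes
    x <- lg
    for (cl in free) x[cls == cl] <- x[cls == cl] - offsets[[cl]]
    .monotone_rss(x, dev)
  }

  if (length(free) == 0) {
    obj <- rss(numeric(0))
    best <- stats::setNames(numeric(0), character(0))
  } else {
    ## exhaustive grid over all free classes (classes are few)
    combos <- expand.grid(rep(list(grid), length(free)))
    names(combos) <- free
    vals <- apply(combos, 1, function(o) rss(as.list(o)))
    start <- as.numeric(combos[which.min(vals), ])
    if (length(free) == 1) {
      opt <- stats::optimize(function(o) rss(stats::setNames(list(o), free)),
                             interval = start + c(-0.1, 0.1))
      best <- stats::setNames(opt$minimum, free)
      obj <- opt$objective
    } else {
      opt <- stats::optim(start, function(o)
        rss(stats::setNames(as.list(o), free)),
        method = "Nelder-Mead",
        control = list(reltol = 1e-10, maxit = 500))
      best <- stats::setNames(opt$par, free)
      obj <- opt$value
    }
  }

  scales <- stats::setNames(rep(1, length(keep)), keep)
  scales[names(best)] <- 10^best
  g_ref <- exp(mean(log(df$gamma_cr1[cls == reference_class])))
  gamma_char <- scales * g_ref

  x <- lg
  for (cl in free) x[cls == cl] <- x[cls == cl] - best[[cl]]
  ord <- order(x)
  iso <- stats::isoreg(x[ord], -dev[ord])
  trend <- data.frame(log10_gamma_rescaled = x[ord], dev = dev[ord],
                      fit = -iso$yf)
  structure(list(scales = scales, gamma_char = gamma_char,
                 reference_class = reference_class, objective = obj,
                 trend = trend, classes_used = keep),
            class = "collapse_result")
}

## RSS of the best non-increasing trend through (x, y)
.monotone_rss <- function(x, y) {
  ord <- order(x)
  iso <- stats::isoreg(x[ord], -y[ord])
  sum((iso$yf - iso$y)^2)
}

#' @export
print.collapse_result <- function(x, ...) {
  cat("Critical-strain collapse (reference:", x$reference_class, ")\n")
  for (cl in names(x$scales))
    cat(sprintf("  %-13s scale = %.3g   gamma_char = %.3g\n",
                cl, x$scales[[cl]], x$gamma_char[[cl]]))
  cat(sprintf("  objective (RSS) = %.4g\n", x$objective))
  invisible(x)
}

#' Extract the tan(delta) printability window
#'
#' The window is the range of `tan_delta` over inks printing accurately,
#' i.e. with `dev` below the threshold; at least `min_support` such inks
#' are required.
#'
#' @param records an [ink_records()] table with `tan_delta` and `dev`.
#' @param dev_threshold accuracy threshold (default 0.1).
#' @param min_support minimum number of passing inks (default 2).
#' @return An object of class `print_window`: `tan_delta_low`,
#'   `tan_delta_high`, `n_pass`, `dev_threshold`, `min_support`.
#' @export
extract_window <- function(records, dev_threshold = 0.1, min_support = 2) {
  stopifnot(inherits(records, "ink_records"))
  if (is.null(records$dev) || is.null(records$tan_delta))
    stop("records need dev and tan_delta columns")
  ok <- !is.na(records$dev) & !is.na(records$tan_delta) &
    records$dev < dev_threshold
  if (sum(ok) < min_support)
    stop(sprintf("only %d ink(s) below dev = %g (min_support = %d)",
                 sum(ok), dev_threshold, min_support))
  structure(list(tan_delta_low = min(records$tan_delta[ok]),
                 tan_delta_high = max(records$tan_delta[ok]),
                 n_pass = sum(ok), dev_threshold = dev_threshold,
                 min_support = min_support),
            class = "print_window")
}

#' @export
print.print_window <- function(x, ...) {
  cat(sprintf("Printability window: %.3g < tan(delta) < %.3g (%d inks with Dev < %g)\n",
              x$tan_delta_low, x$tan_delta_high, x$n_pass, x$dev_threshold))
  invisible(x)
}

#' Full correlation report between rheology and printability
#'
#' Computes the standard panel set, per class and pooled:
#' `gamma_cr1 ~ gamma_cr2`, `n1 ~ n2`, print force against `sigma_y`,
#' `tan_delta` and `n2`, `dev` against `sigma_y`, `tan_delta` and `n2`, and
#' `tan_delta ~ n2`.  Panels that fail (too few records, zero variance,
#' non-positive values under a log axis) are reported as rows with `NA`
#' statistics and the error message in `note`; the report never aborts.
#'
#' @param records an [ink_records()] table.
#' @param subsets subsets to compute; default pooled plus every class
#'   present.
#' @return data.frame with one row per panel and subset: `y`, `x`,
#'   `subset`, `n`, `slope`, `intercept`, `r2`, `transform_x`,
#'   `transform_y`, `note`.
#' @export
correlation_report <- function(records, subsets = NULL) {
  stopifnot(inherits(records, "ink_records"))
  panels <- list(c("gamma_cr1", "gamma_cr2"), c("n2", "n1"),
                 c("sigma_y", "print_force"), c("tan_delta", "print_force"),
                 c("n2", "print_force"), c("sigma_y", "dev"),
                 c("tan_delta", "dev"), c("n2", "dev"), c("n2", "tan_delta"))
  subsets <- subsets %||% c(list(NULL),
                            as.list(stats::na.omit(unique(records$ink_class))))
  rows <- list()
  for (p in panels) for (s in subsets) {
    res <- tryCatch(pairwise_regression(records, x = p[1], y = p[2],
                                        subset = s),
                    error = function(e) conditionMessage(e))
    rows[[length(rows) + 1]] <-
      if (is.character(res))
        data.frame(y = p[2], x = p[1], subset = s %||% "pooled",
                   n = NA_integer_, slope = NA_real_, intercept = NA_real_,
                   r2 = NA_real_, transform_x = NA_character_,
                   transform_y = NA_character_, note = res)
      else
        data.frame(y = res$y, x = res$x, subset = res$subset, n = res$n,
                   slope = res$slope, intercept = res$intercept, r2 = res$r2,
                   transform_x = res$transform[["x"]],
                   transform_y = res$transform[["y"]], note = "")
  }
  do.call(rbind, rows)
}
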