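#' Ordinary least-squares regression with the study's transformations
#'
#' Fits `transform_y(y) ~ transform_x(x)` by OLS and reports, besides the
#' usual slope/intercept/F/R-squared summaries, a two-sided t test of the
#' null hypothesis that the slope equals 1 — a slope indistinguishable from
#' 1 together with a high coefficient of determination is how the study
#' reads "this descriptor is unaffected by the choice of strength measure".
#'
#' Both the raw and the adjusted R-squared are reported; the adjusted value
#' is what matches the study's printed coefficients of determination.
#'
#' @param x,y numeric vectors of equal length (n >= 3 finite pairs after
#'   transformation)
#' @param transform_x,transform_y one of `"identity"`, `"log"`,
#'   `"arcsin_sqrt"` (requires values in \[0, 1\]), `"sqrt"`
#' @param labels optional names for the observations, used in error messages
#' @return object of class `descriptor_regression`: list with `slope`,
#'   `slope_se`, `intercept`, `F`, `df` (c(1, n-2)), `p_value`, `r2`,
#'   `r2_adj`, `p_slope_vs_1`, `n`, `transforms`, and the underlying `lm`
#'   fit as `model`.
#' @examples
#' fit <- fit_regression(c(1, 2, 4, 8), c(1.1, 2, 3.9, 8.2),
#'                       transform_x = "log", transform_y = "log")
#' fit
#' @export
fit_regression <- function(x, y, transform_x = "identity",
                           transform_y = "identity", labels = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(labels)) labels <- as.character(seq_along(x))
  tx <- apply_transform(x, transform_x, labels, "x")
  ty <- apply_transform(y, transform_y, labels, "y")
  ok <- is.finite(tx) & is.finite(ty)
  if (sum(ok) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  fit <- stats::lm(ty ~ tx, subset = ok)
  # exact fits (e.g. comparing a network against itself) are legitimate here;
  # silence summary.lm's perfect-fit warning, the zero-SE case is handled below
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  n <- sum(ok)
  slope <- unname(stats::coef(fit)[2])
  se <- s$coefficients[2, 2]
  p_slope_vs_1 <- if (se == 0) {
    if (isTRUE(all.equal(slope, 1))) 1 else 0
  } else {
    2 * stats::pt(-abs((slope - 1) / se), df = n - 2)
  }
  out <- list(
    slope = slope, slope_se = se,
    intercept = unname(stats::coef(fit)[1]),
    F = unname(s$fstatistic[1]), df = c(1, n - 2),
    p_value = unname(stats::pf(s$fstatistic[1], 1, n - 2, lower.tail = FALSE)),
    r2 = s$r.squared, r2_adj = s$adj.r.squared,
    p_slope_vs_1 = p_slope_vs_1, n = n,
    transforms = c(x = transform_x, y = transform_y),
    model = fit
  )
  class(out) <- "descriptor_regression"
  out
}

apply_transform <- function(v, transform, labels, axis) {
  transform <- match.arg(transform, c("identity", "log", "arcsin_sqrt", "sqrt"))
  switch(transform,
    identity = v,
    log = {
      bad <- is.finite(v) & v <= 0
      if (any(bad)) {
        stop(sprintf("log transform of nonpositive %s value(s) for: %s", axis,
                     paste(labels[bad], collapse = ", ")), call. = FALSE)
      }
      log(v)
    },
    arcsin_sqrt = {
      bad <- is.finite(v) & (v < 0 | v > 1)
      if (any(bad)) {
        stop(sprintf("arcsin_sqrt transform needs %s in [0, 1]; violated for: %s",
                     axis, paste(labels[bad], collapse = ", ")), call. = FALSE)
      }
      asin(sqrt(v))
    },
    sqrt = {
      bad <- is.finite(v) & v < 0
      if (any(bad)) {
        stop(sprintf("sqrt transform of negative %s value(s) for: %s", axis,
                     paste(labels[bad], collapse = ", ")), call. = FALSE)
      }
      sqrt(v)
    }
  )
}

#' @export
print.descriptor_regression <- function(x, ...) {
  cat(sprintf("OLS regression (n = %d; x: %s, y: %s)\n", x$n,
              x$transforms["x"], x$transforms["y"]))
  cat(sprintf("  slope %.4g +/- %.3g (SE), intercept %.4g\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g, R2 = %.3g (adj. %.3g)\n",
              x$df[1], x$df[2], x$F, x$p_value, x$r2, x$r2_adj))
  cat(sprintf("  H0 slope = 1: p = %.3g\n", x$p_slope_vs_1))
  invisible(x)
}

regression_row <- function(fit) {
  data.frame(slope = fit$slope, slope_se = fit$slope_se,
             intercept = fit$intercept, F = fit$F,
             df1 = fit$df[1], df2 = fit$df[2], p_value = fit$p_value,
             r2 = fit$r2, r2_adj = fit$r2_adj,
             p_slope_vs_1 = fit$p_slope_vs_1, n = fit$n)
}

#' Compare species descriptors between the two strength measures
#'
#' Runs, per species descriptor and trophic level, (a) the regression of the
#' visit-based value on the encounter-based value with the study's
#' transformations — species strength log-log on both axes, plant d'
#' arcsin(sqrt) on both axes, everything else untransformed — and (b), for
#' plants, the regression of the ratio of change (visit-based value divided
#' by encounter-based value; log-transformed for strength ratios,
#' square-root-transformed for d' ratios) on log floral display.
#'
#' Species with a zero encounter-based value in a ratio are dropped with a
#' warning.
#'
#' @param encounter_metrics,visit_metrics outputs of [species_metrics()] for
#'   the encounter- and visit-based networks (matched species)
#' @param traits data frame `plant, floral_display`
#' @return list with data frames `measure_comparison` (descriptor x level)
#'   and `display_regressions` (plant descriptor change ratios vs floral
#'   display), plus `fits`, the underlying `descriptor_regression` objects.
#' @export
descriptor_change_analysis <- function(encounter_metrics, visit_metrics,
                                       traits) {
  descriptors <- c("strength", "push_pull", "d_prime")
  fits <- list()
  rows <- list()
  for (lev in c("plant", "pollinator")) {
    e <- encounter_metrics[encounter_metrics$level == lev, ]
    v <- visit_metrics[visit_metrics$level == lev, ]
    common <- intersect(e$species, v$species)
    e <- e[match(common, e$species), ]
    v <- v[match(common, v$species), ]
    for (d in descriptors) {
      tr <- if (d == "strength") c("log", "log")
            else if (d == "d_prime" && lev == "plant")
              c("arcsin_sqrt", "arcsin_sqrt")
            else c("identity", "identity")
      fit <- fit_regression(e[[d]], v[[d]], transform_x = tr[1],
                            transform_y = tr[2], labels = common)
      id <- paste(lev, d, sep = ".")
      fits[[id]] <- fit
      rows[[id]] <- cbind(data.frame(level = lev, descriptor = d,
                                     stringsAsFactors = FALSE),
                          regression_row(fit))
    }
  }
  measure_comparison <- do.call(rbind, rows)
  rownames(measure_comparison) <- NULL

  e <- encounter_metrics[encounter_metrics$level == "plant", ]
  v <- visit_metrics[visit_metrics$level == "plant", ]
  common <- intersect(intersect(e$species, v$species), traits$plant)
  e <- e[match(common, e$species), ]
  v <- v[match(common, v$species), ]
  display <- traits$floral_display[match(common, traits$plant)]
  disp_rows <- list()
  for (d in descriptors) {
    enc_val <- e[[d]]
    zero <- enc_val == 0
    if (any(zero)) {
      warning(sprintf("dropping %d plant(s) with zero encounter-based %s from the ratio regression: %s",
                      sum(zero), d, paste(common[zero], collapse = ", ")),
              call. = FALSE)
    }
    ratio <- (v[[d]] / enc_val)[!zero]
    tr_y <- switch(d, strength = "log", d_prime = "sqrt", "identity")
    fit <- fit_regression(display[!zero], ratio, transform_x = "log",
                          transform_y = tr_y, labels = common[!zero])
    id <- paste("ratio", d, sep = ".")
    fits[[id]] <- fit
    disp_rows[[id]] <- cbind(data.frame(descriptor = d,
                                        stringsAsFactors = FALSE),
                             regression_row(fit))
  }
  display_regressions <- do.call(rbind, disp_rows)
  rownames(display_regressions) <- NULL

  list(measure_comparison = measure_comparison,
       display_regressions = display_regressions, fits = fits)
}

#' Bootstrap comparison of network descriptors between strength measures
#'
#' Subsamples the pool of observed encounter events (without replacement by
#' default), rebuilds the encounter-based network through the full weekly
#' weighting pipeline using the complete flower-survey table, converts it to
#' a visit-based network with the given visit estimates (exclusions applied
#' to both), computes the five network descriptors on each, and compares the
#' paired replicates with two-sided paired t tests — once per subsampling
#' fraction. Replicates in which either trophic level collapses below two
#' species are redrawn (tallied in `n_redraws`).
#'
#' Replicate pairs with identical descriptor values throughout (e.g.
#' `fractions = 1`) have zero-variance differences; the t statistic and
#' p-value are reported as `NA` in that case.
#'
#' @param encounters data frame `week, plant, pollinator`, one row per event
#' @param flower_surveys data frame `week, plant, flowers_surveyed,
#'   flower_abundance`
#' @param visit_estimates output of [estimate_visits()] covering the
#'   interactions of the full network
#' @param fractions subsampling intensities, each in (0, 1\]
#' @param n_reps replicates per fraction (the study design uses 100)
#' @param seed integer seed fixing the random stream; identical seed and
#'   inputs give bit-identical output
#' @param replace draw with replacement instead (a resample rather than a
#'   subsample)
#' @param ie_denominator passed to [interaction_evenness()]
#' @param max_redraws cap on redraws per replicate before erroring
#' @return data frame with one row per descriptor x fraction: replicate
#'   means and SDs under both measures, the paired t statistic and p-value,
#'   `n_reps` and `n_redraws`. The per-replicate descriptor values are
#'   attached as attribute `"replicates"`.
#' @export
bootstrap_compare <- function(encounters, flower_surveys, visit_estimates,
                              fractions = c(0.25, 0.5, 0.75), n_reps = 100,
                              seed = NULL, replace = FALSE,
                              ie_denominator = "potential",
                              max_redraws = 100) {
  stopifnot(all(fractions > 0), all(fractions <= 1), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_events <- nrow(encounters)
  descriptors <- c("wnodf", "h2_prime", "interaction_evenness",
                   "plant_generality", "pollinator_generality")
  rep_rows <- list()
  out_rows <- list()
  for (f in fractions) {
    k <- floor(f * n_events)
    if (k < 1L) stop("fraction ", f, " leaves no events", call. = FALSE)
    enc_vals <- vis_vals <- matrix(NA_real_, n_reps, length(descriptors),
                                   dimnames = list(NULL, descriptors))
    n_redraws <- 0L
    for (r in seq_len(n_reps)) {
      repeat {
        idx <- sample.int(n_events, k, replace = replace)
        sub <- encounters[idx, , drop = FALSE]
        nets <- tryCatch({
          wf <- weekly_encounter_frequency(sub, flower_surveys)
          enc <- encounter_strength(wf, flower_surveys)
          visit_strength(enc, visit_estimates)
        }, error = function(e) NULL)
        ok <- !is.null(nets) &&
          nrow(nets$encounter$W) >= 2L && ncol(nets$encounter$W) >= 2L &&
          nrow(nets$visit$W) >= 2L && ncol(nets$visit$W) >= 2L
        if (ok) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_redraws) {
          stop("too many degenerate replicates at fraction ", f, call. = FALSE)
        }
      }
      enc_vals[r, ] <- unlist(network_metrics(nets$encounter,
                                              ie_denominator)[descriptors])
      vis_vals[r, ] <- unlist(network_metrics(nets$visit,
                                              ie_denominator)[descriptors])
    }
    for (d in descriptors) {
      diffs <- vis_vals[, d] - enc_vals[, d]
      if (n_reps >= 2L && stats::sd(diffs) > 0) {
        tt <- stats::t.test(vis_vals[, d], enc_vals[, d], paired = TRUE)
        t_stat <- unname(tt$statistic); p_val <- tt$p.value
      } else {
        t_stat <- NA_real_; p_val <- NA_real_
      }
      out_rows[[paste(d, f)]] <- data.frame(
        descriptor = d, fraction = f,
        encounter_mean = mean(enc_vals[, d]),
        encounter_sd = stats::sd(enc_vals[, d]),
        visit_mean = mean(vis_vals[, d]),
        visit_sd = stats::sd(vis_vals[, d]),
        paired_t = t_stat, p_value = p_val,
        n_reps = n_reps, n_redraws = n_redraws,
        stringsAsFactors = FALSE)
    }
    rep_rows[[as.character(f)]] <- list(encounter = enc_vals, visit = vis_vals)
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- rep_rows
  out
}
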