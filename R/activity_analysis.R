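#' Condition-level activity profiles
#'
#' For every component, collects the per-sample activities and the mean
#' activity of each experimental condition (the bar heights of the activity
#' bar graph; samples are the dots). Conditions are ordered grouped by
#' project, in order of first appearance in the metadata.
#'
#' @param A Components-by-samples activity matrix.
#' @param metadata Sample metadata (`sample_id`, `condition_id`,
#'   `project_id`).
#' @return A list of `activity_profile` objects: `component_id`,
#'   `per_sample` (named vector), `per_condition_mean` (named vector in
#'   project-grouped order), `condition_project` (named project lookup),
#'   `project_order`.
#' @export
condition_activities <- function(A, metadata) {
  miss <- setdiff(colnames(A), metadata$sample_id)
  if (length(miss))
    stop("samples absent from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- metadata[match(colnames(A), metadata$sample_id), ]
  project_order <- unique(meta$project_id)
  cond_df <- unique(meta[, c("condition_id", "project_id")])
  cond_df <- cond_df[order(match(cond_df$project_id, project_order)), ]
  conds <- cond_df$condition_id
  lapply(rownames(A), function(id) {
    per_sample <- A[id, ]
    means <- vapply(conds, function(cc)
      mean(per_sample[meta$condition_id == cc]), 1.0)
    structure(list(component_id = id,
                   per_sample = per_sample,
                   per_condition_mean = means,
                   condition_project = stats::setNames(cond_df$project_id,
                                                       conds),
                   project_order = project_order),
              class = "activity_profile")
  })
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s: %d samples, %d conditions\n",
              x$component_id, length(x$per_sample),
              length(x$per_condition_mean)))
  invisible(x)
}

# R^2 of a fitted model against observed y.
fit_r2 <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  max(0, 1 - sum((y - fitted)^2) / sst)
}

#' Regulator-expression vs iModulon-activity concordance fit
#'
#' Fits (i) an ordinary least-squares line and (ii) a broken line
#' `y = b` for `x < x0`, `y = b + s (x - x0)` for `x >= x0` -- a hinge
#' capturing regulators that must reach a minimum expression before the
#' correlation appears. The breakpoint `x0` is chosen over the grid of
#' observed regulator-expression values (excluding the two extremes on each
#' side so both segments stay populated) by minimizing the residual sum of
#' squares. Because the line is nested in the broken line, the broken R2 is
#' never lower; the broken model is chosen only when it improves R2 by more
#' than `improvement`.
#'
#' @param activity Numeric vector of iModulon activities per sample (or an
#'   `activity_profile`, whose `per_sample` is used).
#' @param regulator_expression Numeric vector of the regulator gene's
#'   expression in the same samples.
#' @param improvement Minimum R2 gain for choosing the broken line
#'   (default 0.1).
#' @param regulator_gene Label carried into the result.
#' @return A list of class `regulator_fit`: `regulator_gene`, `model`
#'   (`"line"` or `"broken_line"`), `breakpoint_x0` (NA for a line),
#'   `slope`, `intercept`, `r2_line`, `r2_broken`, `chosen_r2`.
#' @export
regulator_correlation <- function(activity, regulator_expression,
                                  improvement = 0.1,
                                  regulator_gene = NA_character_) {
  y <- if (inherits(activity, "activity_profile")) activity$per_sample
       else activity
  x <- regulator_expression
  if (length(x) != length(y))
    stop("activity and regulator expression differ in length", call. = FALSE)
  if (length(x) < 5L)
    stop("need at least 5 paired points", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(list(regulator_gene = regulator_gene, model = "line",
                          breakpoint_x0 = NA_real_, slope = 0,
                          intercept = mean(y), r2_line = 0, r2_broken = 0,
                          chosen_r2 = 0),
                     class = "regulator_fit"))
  }
  line <- stats::lm.fit(cbind(1, x), y)
  r2_line <- fit_r2(y, y - line$residuals)

  xs <- sort(unique(x))
  # interior breakpoints keep both segments populated; the minimum-x
  # candidate reduces the hinge to the plain line, so the broken family
  # nests the line and r2_broken >= r2_line always
  grid <- if (length(xs) > 4L) c(xs[1L], xs[3:(length(xs) - 2L)]) else xs
  best <- NULL
  for (x0 in grid) {
    h <- pmax(0, x - x0)
    fit <- stats::lm.fit(cbind(1, h), y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(x0 = x0, sse = sse, coef = fit$coefficients,
                   fitted = y - fit$residuals)
  }
  r2_broken <- fit_r2(y, best$fitted)
  broken <- (r2_broken - r2_line) > improvement
  structure(list(regulator_gene = regulator_gene,
                 model = if (broken) "broken_line" else "line",
                 breakpoint_x0 = if (broken) best$x0 else NA_real_,
                 slope = if (broken) unname(best$coef[2L])
                         else unname(line$coefficients[2L]),
                 intercept = if (broken) unname(best$coef[1L])
                             else unname(line$coefficients[1L]),
                 r2_line = r2_line, r2_broken = r2_broken,
                 chosen_r2 = if (broken) r2_broken else r2_line),
            class = "regulator_fit")
}

#' @export
print.regulator_fit <- function(x, ...) {
  cat(sprintf("<regulator_fit> %s: model %s, R2 = %.3f%s\n",
              x$regulator_gene, x$model, x$chosen_r2,
              if (x$model == "broken_line")
                sprintf(", x0 = %.3g", x$breakpoint_x0) else ""))
  invisible(x)
}
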