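# First-order mRNA decay fitting from metabolic-labeling (T->C)
# conversion rates over a labeling time course.

#' Fit first-order decay kinetics to conversion-rate time courses
#'
#' Under first-order turnover, the labeled fraction approaches its
#' plateau as `c(t) = c_max * (1 - exp(-k * t))`, where `k` is the
#' decay rate (per minute) and the mRNA half-life is `ln(2)/k`.
#' Conversion rates are first averaged per timepoint, weighted by read
#' counts; the saturating curve is then fit by weighted nonlinear least
#' squares with the plateau `c_max` as a free asymptote (initialized
#' from a log-linear regression of `log(1 - c/c_hat_max)` on `t`, with
#' `c_hat_max` set to 1.05 times the largest observed rate, which also
#' serves as the fallback when the nonlinear fit fails to converge).
#'
#' Fits are flagged: `"nonincreasing"` when the per-timepoint means do
#' not increase (no kinetic signal), `"no_conversion"` (infinite
#' half-life) when conversion is zero throughout, and
#' `"low_confidence"` when the half-life is shorter than the first
#' nonzero timepoint (the curve saturates before it is sampled).
#'
#' @param conversions Tibble with columns `time` (minutes), `rate`
#'   (conversion rate in `[0, 1]`), optional `weight` (read counts) and
#'   optional `isoform_id` (fits are per isoform). At least 3
#'   timepoints with positive weight are required.
#' @return A `halflife_fit` tibble: `isoform_id`, `k` (per minute),
#'   `half_life` (minutes), `c_max`, `converged`, `flag`.
#' @examples
#' t <- c(0, 120, 240, 360)
#' curve <- tibble::tibble(time = t, rate = 0.1 * (1 - exp(-0.005 * t)))
#' fit_half_life(curve)$half_life  # ~ log(2)/0.005 = 138.63
#' @export
fit_half_life <- function(conversions) {
  cv <- as_tibble(conversions)
  if (!"weight" %in% names(cv)) cv$weight <- 1
  if (!"isoform_id" %in% names(cv)) cv$isoform_id <- "isoform"
  res <- purrr::map_dfr(split(cv, cv$isoform_id), function(d) {
    # weighted mean conversion rate per timepoint
    pt <- d |>
      filter(.data$weight > 0) |>
      group_by(time = .data$time) |>
      summarise(rate = sum(.data$rate * .data$weight) / sum(.data$weight),
                weight = sum(.data$weight), .groups = "drop") |>
      arrange(.data$time)
    if (nrow(pt) < 3) stop("need >= 3 timepoints with positive weights")
    base <- tibble(isoform_id = d$isoform_id[1], k = NA_real_,
                   half_life = NA_real_, c_max = NA_real_,
                   converged = FALSE, flag = NA_character_)
    if (all(pt$rate == 0)) {
      base$half_life <- Inf
      base$flag <- "no_conversion"
      return(base)
    }
    nonincreasing <- all(diff(pt$rate) <= 0)
    cmax0 <- max(pt$rate) * 1.05
    pos <- pt$rate < cmax0 & pt$time > 0
    k0 <- tryCatch({
      f <- lm(log(1 - rate / cmax0) ~ 0 + time, data = pt[pos, ],
              weights = pt$weight[pos])
      max(-unname(coef(f)[1]), 1e-6)
    }, error = function(e) 1e-3)
    fit <- tryCatch(
      minpack.lm::nlsLM(rate ~ cmax * (1 - exp(-k * time)), data = pt,
                        weights = pt$weight,
                        start = list(cmax = cmax0, k = k0),
                        lower = c(1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      base$k <- k0
      base$c_max <- cmax0
      base$converged <- FALSE
    } else {
      co <- coef(fit)
      base$k <- unname(co["k"])
      base$c_max <- unname(co["cmax"])
      base$converged <- TRUE
    }
    base$half_life <- log(2) / base$k
    first_t <- min(pt$time[pt$time > 0])
    base$flag <- if (nonincreasing) "nonincreasing"
      else if (base$half_life < first_t) "low_confidence"
      else NA_character_
    base
  })
  class(res) <- c("halflife_fit", class(res))
  res
}

#' @method tidy halflife_fit
#' @export
tidy.halflife_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "halflife_fit")
  as_tibble(out)
}

#' @method glance halflife_fit
#' @export
glance.halflife_fit <- function(x, ...) {
  tibble(n_isoforms = nrow(x), n_converged = sum(x$converged),
         n_flagged = sum(!is.na(x$flag)))
}
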