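#' Convert a yield-table stand curve to whole-tree carbon
#'
#' Production (yield) tables report standing volume and current annual
#' increment of exploitable wood (stem and large branches) only. Volumes are
#' converted to carbon with the group's wood density and the 0.47 carbon
#' fraction, then expanded to whole-tree biomass by dividing by the
#' extracted organs' share of total biomass. Stand NPP is the expanded wood
#' increment plus the turnover production of every organ with a nonzero
#' turnover rate applied to the expanded stock, so that at stand level
#' NPP minus natural mortality equals the biomass increment exactly.
#'
#' @param curve A data frame with columns `age` (years, increasing),
#'   `volume` (m3/ha standing) and `increment` (m3 ha-1 yr-1 current annual
#'   increment).
#' @param group `"deciduous"` or `"coniferous"`.
#' @param registry An [organ_registry()].
#' @return A tibble with columns `age`, `biomass_c` (t C/ha whole tree) and
#'   `npp_c` (t C ha-1 yr-1).
#' @export
stand_to_carbon <- function(curve, group, registry = organ_registry()) {
  curve <- as_tibble(curve)
  assert_group(group)
  if (any(curve$volume < 0) || any(curve$increment < 0)) {
    abort("standing volume and increment must be >= 0")
  }
  org <- registry$organs[registry$organs$group == group, ]
  exp_share <- sum(org$share[org$extracted])
  if (exp_share <= 0) abort("extracted-organ share must be positive")
  dens <- registry$wood_density[[group]]
  cf <- registry$carbon_fraction
  m <- mortality_rate(registry, group)
  biomass_c <- curve$volume * dens * cf / exp_share
  npp_c <- curve$increment * dens * cf / exp_share + m * biomass_c
  tibble(age = curve$age, biomass_c = biomass_c, npp_c = npp_c)
}

#' Average a carbon stand curve over a rotation-age mosaic
#'
#' A territory exploited at average rotation time `rt` is modelled as `rt`
#' equal-area age classes aged 1..rt; landscape biomass density and NPP are
#' the equal-weight means of the stand curve over those ages, with ages
#' between tabulated rows linearly interpolated.
#'
#' @param carbon_curve A tibble from [stand_to_carbon()].
#' @param rt Rotation time in whole years (`1 <= rt <= max(age)`).
#' @return A one-row tibble with columns `rt`, `biomass_c`, `npp_c`.
#' @export
rotation_average <- function(carbon_curve, rt) {
  rt <- as.integer(rt)
  if (rt < 1) abort("rotation time must be >= 1 year")
  if (rt > max(carbon_curve$age)) {
    abort(paste0("rotation time ", rt, " exceeds the tabulated maximum age ",
                 max(carbon_curve$age), "; extend the production table"))
  }
  ages <- seq_len(rt)
  b <- approx(carbon_curve$age, carbon_curve$biomass_c, xout = ages,
              rule = 2)$y
  n <- approx(carbon_curve$age, carbon_curve$npp_c, xout = ages, rule = 2)$y
  tibble(rt = rt, biomass_c = mean(b), npp_c = mean(n))
}

#' Rotation-averaged points over a range of rotation times
#'
#' Convenience wrapper producing the (biomass, NPP) point cloud that
#' [fit_logistic()] consumes, one point per integer rotation time.
#'
#' @inheritParams rotation_average
#' @param rts Integer vector of rotation times.
#' @return A tibble with columns `rt`, `biomass_c`, `npp_c`.
#' @export
rotation_points <- function(carbon_curve, rts = 20:120) {
  rts <- rts[rts <= max(carbon_curve$age)]
  purrr::map_dfr(rts, rotation_average, carbon_curve = carbon_curve)
}

#' Fit the logistic NPP-biomass relationship
#'
#' Fits `NPP = r * B * (1 - B / K)` to a set of (B, NPP) points. The
#' deterministic reference solver linearises to `NPP/B = r - (r/K) * B` and
#' solves by ordinary least squares on points with `B > 0`; an optional
#' bounded Levenberg-Marquardt pass refines the estimates on the original
#' (unlinearised) residuals.
#'
#' @param points A data frame with columns `biomass_c` and `npp_c`.
#' @param group Optional species-group label carried on the result.
#' @param refine If `TRUE`, refine the linearised solution with
#'   [minpack.lm::nlsLM()] on the untransformed residuals. The linearised
#'   fit remains the deterministic reference (default `FALSE`).
#' @return An object of class `logistic_fit` with elements `r` (1/yr),
#'   `K` (t C/ha), `group`, `fit_residual` (sum of squared NPP residuals),
#'   `n`, `method` and `points`.
#' @export
fit_logistic <- function(points, group = NULL, refine = FALSE) {
  points <- as_tibble(points)
  pts <- points %>% filter(.data$biomass_c > 0)
  if (nrow(pts) < 3) abort("need at least 3 points with positive biomass")
  if (length(unique(pts$biomass_c)) < 2) {
    abort("degenerate fit: all biomass values equal")
  }
  y <- pts$npp_c / pts$biomass_c
  fit <- lm(y ~ pts$biomass_c)
  r <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (!is.finite(r) || r <= 0 || !is.finite(slope) || slope >= 0) {
    abort(paste0("logistic fit failed: linearised intercept/slope (",
                 signif(r, 4), ", ", signif(slope, 4),
                 ") do not give r > 0 and K > 0"))
  }
  K <- -r / slope
  method <- "linearised-ols"
  if (refine) {
    nls_fit <- try(minpack.lm::nlsLM(
      npp_c ~ r * biomass_c * (1 - biomass_c / K),
      data = pts, start = list(r = r, K = K),
      lower = c(r = 1e-6, K = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      cf <- coef(nls_fit)
      r <- unname(cf["r"]); K <- unname(cf["K"])
      method <- "linearised-ols+nlsLM"
    }
  }
  resid <- pts$npp_c - r * pts$biomass_c * (1 - pts$biomass_c / K)
  structure(list(r = r, K = K, group = group,
                 fit_residual = sum(resid^2), n = nrow(pts),
                 method = method, points = points),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>", if (!is.null(x$group)) x$group else "", "\n")
  cat(sprintf("  r = %.4f /yr, K = %.1f t C/ha (n = %d, SS = %.3g, %s)\n",
              x$r, x$K, x$n, x$fit_residual, x$method))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("r", "K"), estimate = c(x$r, x$K),
         unit = c("1/yr", "t C/ha"))
}

#' @rdname fit_logistic
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(r = x$r, K = x$K, fit_residual = x$fit_residual, nobs = x$n,
         method = x$method)
}

#' Area- and class-weighted regional growth parameters
#'
#' Regional `r` and `K` per species group are the weighted arithmetic means
#' of the per-species, per-productivity-class fits, with weights the product
#' of species area shares and the normalised productivity-class
#' distribution.
#'
#' @param fits A data frame with columns `species`, `productivity_class`,
#'   `group`, `r`, `K` (one row per fitted table).
#' @param species_weights A data frame `species`, `weight` with weights
#'   summing to 1 within each group (single-species groups may omit it).
#' @param class_dist A data frame `group`, `productivity_class`, `weight`
#'   of non-negative class weights (e.g. the 0:0:1:4 pattern); normalised
#'   within group before use. `NULL` means equal weights on the classes
#'   present.
#' @return A tibble with columns `group`, `r`, `K`.
#' @export
regional_params <- function(fits, species_weights = NULL, class_dist = NULL) {
  fits <- as_tibble(fits)
  if (is.null(species_weights)) {
    species_weights <- fits %>% distinct(.data$species) %>%
      mutate(weight = 1)
  }
  if (is.null(class_dist)) {
    class_dist <- fits %>%
      distinct(.data$group, .data$productivity_class) %>%
      mutate(weight = 1)
  }
  class_dist <- as_tibble(class_dist)
  if (any(class_dist$weight < 0)) abort("class weights must be >= 0")
  covered <- class_dist %>% filter(.data$weight > 0) %>%
    dplyr::anti_join(fits, by = c("group", "productivity_class"))
  if (nrow(covered) > 0) {
    abort(paste0("positive class weight without a fitted table: group ",
                 paste(covered$group, covered$productivity_class,
                       sep = "/", collapse = ", ")))
  }
  fits %>%
    left_join(as_tibble(species_weights), by = "species") %>%
    left_join(class_dist, by = c("group", "productivity_class"),
              suffix = c("_sp", "_cl")) %>%
    mutate(weight_cl = dplyr::coalesce(.data$weight_cl, 0),
           w = .data$weight_sp * .data$weight_cl) %>%
    group_by(.data$group) %>%
    summarise(r = sum(.data$w * .data$r) / sum(.data$w),
              K = sum(.data$w * .data$K) / sum(.data$w))
}
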