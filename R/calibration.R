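#' Loss of one growth-scaling candidate against inventory targets
#'
#' Runs the biomass simulation with the candidate's anchor scales and
#' returns the sum of squared differences between simulated and observed
#' biomass stocks (t C) over all (year, group) inventory targets.
#' Deciduous and coniferous targets are weighted equally.
#'
#' @param dataset A [regional_dataset()].
#' @param params A data frame `group, r, K` of reference-era growth
#'   parameters.
#' @param targets A data frame `year, group, stock` (t C) of inventory
#'   biomass stocks.
#' @param s0,s1 Named numeric (by group) anchor scales for the start and
#'   end years.
#' @param registry An [organ_registry()].
#' @return The scalar loss (t C)^2; `Inf` with attribute `reason` if the
#'   simulation fails for this candidate.
#' @export
evaluate_candidate <- function(dataset, params, targets, s0, s1,
                               registry = organ_registry()) {
  targets <- as_tibble(targets)
  if (nrow(targets) == 0) abort("no inventory targets supplied")
  mods <- growth_modifiers(s0, s1, start_year = min(dataset$years),
                           end_year = max(dataset$years))
  traj <- try(run_biomass(dataset, params, mods, mode = "dynamic",
                          registry = registry), silent = TRUE)
  if (inherits(traj, "try-error")) {
    out <- Inf
    attr(out, "reason") <- conditionMessage(attr(traj, "condition"))
    return(out)
  }
  sim <- traj %>% select("year", "group", "stock")
  joined <- targets %>% left_join(sim, by = c("year", "group"))
  if (anyNA(joined$stock.y)) abort("target year outside the simulated span")
  sum((joined$stock.x - joined$stock.y)^2)
}

#' Calibrate time-varying growth scaling by exhaustive grid search
#'
#' Evaluates every combination of start- and end-anchor scales on a
#' discrete grid (0.50 to 1.50 in steps of 0.05 by default) against
#' inventory biomass stocks, per species group. Because the two groups'
#' biomass dynamics are fully decoupled, the per-group search is exact for
#' the joint problem at a fraction of the cost. Ties are broken by smaller
#' `|s0 - 1|`, then smaller `|s1 - 1|`, then lexicographically.
#'
#' @inheritParams evaluate_candidate
#' @param grid Numeric vector of candidate scales (default
#'   `seq(0.5, 1.5, by = 0.05)`).
#' @return An object of class `craft_calibration`: a list with `best` (a
#'   tibble `group, s0, s1, loss`), `ranked` (all candidates per group,
#'   ranked), and the matching [growth_modifiers()] in `$modifiers`.
#' @export
calibrate_growth <- function(dataset, params, targets,
                             grid = seq(0.5, 1.5, by = 0.05),
                             registry = organ_registry()) {
  targets <- as_tibble(targets)
  groups <- unique(as_tibble(params)$group)
  per_group <- purrr::map(groups, function(g) {
    tg <- targets %>% filter(.data$group == g)
    if (nrow(tg) == 0) {
      return(tibble(group = g, s0 = 1, s1 = 1, loss = NA_real_,
                    feasible = TRUE))
    }
    cand <- tidyr::expand_grid(s0 = grid, s1 = grid)
    loss <- purrr::map_dbl(seq_len(nrow(cand)), function(i) {
      evaluate_candidate_group(dataset, params, tg, g,
                               cand$s0[i], cand$s1[i], registry)
    })
    cand %>%
      mutate(group = g, loss = loss, feasible = is.finite(loss)) %>%
      select("group", "s0", "s1", "loss", "feasible")
  })
  ranked <- bind_rows(per_group) %>%
    arrange(.data$group, .data$loss, abs(.data$s0 - 1), abs(.data$s1 - 1),
            .data$s0, .data$s1)
  if (all(!ranked$feasible, na.rm = TRUE)) {
    abort("all calibration candidates were infeasible")
  }
  best <- ranked %>% filter(.data$feasible | is.na(.data$loss)) %>%
    group_by(.data$group) %>% slice(1) %>% ungroup()
  mods <- growth_modifiers(
    s0 = setNames(best$s0, best$group)[SPECIES_GROUPS[SPECIES_GROUPS %in% best$group]],
    s1 = setNames(best$s1, best$group)[SPECIES_GROUPS[SPECIES_GROUPS %in% best$group]],
    start_year = min(dataset$years), end_year = max(dataset$years)
  )
  structure(list(best = best, ranked = ranked, modifiers = mods,
                 targets = targets, grid = grid),
            class = "craft_calibration")
}

# Single-group candidate loss on the lean density integrator (the groups
# are dynamically independent, so nothing else needs simulating).
evaluate_candidate_group <- function(dataset, params, targets, group,
                                     s0, s1, registry) {
  p <- as_tibble(params) %>% filter(.data$group == !!group)
  if (nrow(p) != 1) abort(paste0("missing growth parameters for ", group))
  years <- dataset$years
  area <- dataset$area$value[dataset$area$group == group]
  harv <- dataset$harvest$value[dataset$harvest$group == group]
  m <- mortality_rate(registry, group)
  rat <- residue_ratios(registry, group)
  h_total <- ifelse(area > 0, harv / area, 0) * (1 + rat$total)
  sc <- scale_at(growth_modifiers(
    setNames(rep(s0, 2), SPECIES_GROUPS),
    setNames(rep(s1, 2), SPECIES_GROUPS),
    start_year = min(years), end_year = max(years)), years, group)
  b <- try(integrate_density(years, area, h_total, p$r * sc, p$K * sc, m),
           silent = TRUE)
  if (inherits(b, "try-error")) return(Inf)
  idx <- match(targets$year, years)
  if (anyNA(idx)) abort("target year outside the simulated span")
  sum((targets$stock - b[idx] * area[idx])^2)
}

#' @export
print.craft_calibration <- function(x, ...) {
  cat("<craft_calibration> grid", min(x$grid), "to", max(x$grid),
      "step", signif(diff(x$grid[1:2]), 3), "\n")
  for (i in seq_len(nrow(x$best))) {
    b <- x$best[i, ]
    cat(sprintf("  %s: s0 = %.2f, s1 = %.2f (loss %.4g)\n",
                b$group, b$s0, b$s1, b$loss))
  }
  invisible(x)
}

#' @rdname calibrate_growth
#' @param x A `craft_calibration`.
#' @param ... Unused.
#' @method tidy craft_calibration
#' @export
tidy.craft_calibration <- function(x, ...) x$ranked

#' @rdname calibrate_growth
#' @method glance craft_calibration
#' @export
glance.craft_calibration <- function(x, ...) {
  x$best %>%
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("s0", "s1", "loss"))
}

#' Calibrate the productivity-class distribution
#'
#' Yield tables stratify stands into productivity classes but the
#' historical statistics do not say how the forest area is distributed
#' across them. The distribution is fitted by exhaustive search over small
#' integer weight vectors (entries from `weight_values` per class),
#' evaluating each implied `(r, K)` through the biomass simulation at
#' scale = 1 against the earliest inventory target year, per group.
#'
#' @inheritParams evaluate_candidate
#' @param fits Per-species, per-class logistic fits as taken by
#'   [regional_params()].
#' @param species_weights Species area weights (see [regional_params()]).
#' @param weight_values Candidate entries for each class weight (default
#'   `c(0, 1, 2, 4, 8)`).
#' @param modifiers Growth scaling applied while evaluating candidates
#'   (default scale = 1, i.e. the distribution is fitted before the
#'   scaling); pass fitted modifiers to re-fit the distribution given a
#'   scaling.
#' @param target_years Target years entering the loss (default: the
#'   earliest target year).
#' @return A list with `best` (tibble `group, weights, loss`),
#'   `class_dist` (tidy weights), `params` (the implied `group, r, K`
#'   tibble), and `ranked`.
#' @export
calibrate_class_distribution <- function(dataset, fits, targets,
                                         species_weights = NULL,
                                         weight_values = c(0, 1, 2, 4, 8),
                                         modifiers = NULL,
                                         target_years = NULL,
                                         registry = organ_registry()) {
  fits <- as_tibble(fits)
  targets <- as_tibble(targets)
  if (is.null(target_years)) target_years <- min(targets$year)
  groups <- unique(fits$group)
  res <- purrr::map(groups, function(g) {
    fg <- fits %>% filter(.data$group == g)
    classes <- sort(unique(fg$productivity_class))
    # species-weighted (r, K) per class, so candidate params are plain
    # weighted means over the class axis
    sw <- if (is.null(species_weights)) {
      fg %>% distinct(.data$species) %>% mutate(weight = 1)
    } else as_tibble(species_weights)
    by_class <- fg %>%
      left_join(sw, by = "species") %>%
      group_by(.data$productivity_class) %>%
      summarise(r = sum(.data$weight * .data$r) / sum(.data$weight),
                K = sum(.data$weight * .data$K) / sum(.data$weight)) %>%
      arrange(.data$productivity_class)
    combos <- as.matrix(do.call(
      tidyr::expand_grid,
      setNames(rep(list(weight_values), length(classes)),
               paste0("w", classes))))
    combos <- combos[rowSums(combos) > 0, , drop = FALSE]
    tg <- targets %>%
      filter(.data$group == g, .data$year %in% target_years)
    s0g <- if (is.null(modifiers)) 1 else modifiers$s0[[g]]
    s1g <- if (is.null(modifiers)) 1 else modifiers$s1[[g]]
    loss <- vapply(seq_len(nrow(combos)), function(i) {
      w <- combos[i, ] / sum(combos[i, ])
      p <- tibble(group = g, r = sum(w * by_class$r),
                  K = sum(w * by_class$K))
      evaluate_candidate_group(dataset, p, tg, g, s0g, s1g, registry)
    }, numeric(1))
    ord <- order(loss, apply(combos, 1, paste, collapse = ":"))
    list(group = g, classes = classes,
         combos = combos[ord, , drop = FALSE], loss = loss[ord])
  })
  best <- purrr::map_dfr(res, function(x) {
    tibble(group = x$group,
           weights = paste(as.numeric(x$combos[1, ]), collapse = ":"),
           loss = x$loss[1])
  })
  class_dist <- purrr::map_dfr(res, function(x) {
    tibble(group = x$group, productivity_class = x$classes,
           weight = as.numeric(x$combos[1, ]))
  })
  params <- regional_params(fits, species_weights, class_dist)
  ranked <- purrr::map_dfr(res, function(x) {
    tibble(group = x$group,
           weights = apply(x$combos, 1, paste, collapse = ":"),
           loss = x$loss)
  })
  list(best = best, class_dist = class_dist, params = params,
       ranked = ranked)
}

#' Full sequential calibration: class distribution, then growth scaling
#'
#' The reference sequential procedure: (1) fit the productivity-class
#' distribution with the growth scaling frozen at 1, (2) fit the scaling
#' anchors by grid search given that distribution, then (3) optionally
#' re-fit the distribution given the fitted scaling and re-fit the scaling
#' (`rounds = 2`, the default, is one such refinement; the loss is
#' non-increasing over rounds).
#'
#' @inheritParams calibrate_class_distribution
#' @inheritParams calibrate_growth
#' @param rounds Number of alternating rounds (>= 1).
#' @return A list with `class_dist`, `params`, `scaling` (a
#'   `craft_calibration`), and `modifiers`.
#' @export
calibrate_craft <- function(dataset, fits, targets, species_weights = NULL,
                            weight_values = c(0, 1, 2, 4, 8),
                            grid = seq(0.5, 1.5, by = 0.05), rounds = 2,
                            registry = organ_registry()) {
  stopifnot(rounds >= 1)
  mods <- NULL
  cd <- NULL
  scaling <- NULL
  for (i in seq_len(rounds)) {
    cd <- calibrate_class_distribution(
      dataset, fits, targets, species_weights, weight_values,
      modifiers = mods, registry = registry)
    scaling <- calibrate_growth(dataset, cd$params, targets, grid,
                                registry = registry)
    mods <- scaling$modifiers
  }
  list(class_dist = cd$class_dist, params = cd$params, scaling = scaling,
       modifiers = mods)
}
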