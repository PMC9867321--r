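#' Patty formulation metadata for the four regulatory categories
#'
#' Returns the recipe metadata for the four South African raw-patty
#' categories: P1 premium "ground patty" (total meat >= 99.6%), P2 regular
#' "burger patty" (>= 70% meat, species substitutions allowed), P3
#' "value burger" (>= 55% total meat, textured vegetable protein extender)
#' and P4 "econo/budget burger" (>= 35% total meat, mechanically recovered
#' meat). Each category carries its treatments: P1 varies added beef fat
#' (ten levels, 0-40%), P2 varies the substituted species and level (beef
#' control plus pork/lamb/ostrich at three levels each), and P3/P4 vary the
#' declared total-meat percentage (five levels each). Total meat (TM%) and
#' total meat equivalent (TME%) values are carried exactly as published for
#' P3 and P4 and are never recomputed; authenticity flags whether a treatment
#' complies with the regulation.
#'
#' @return A data.frame with one row per (category, treatment): columns
#'   `category` (factor P1-P4), `treatment` (label), `tm_percent`,
#'   `tme_percent` (NA where the category's table does not declare them) and
#'   `authenticity` ("authentic", "adulterated" or "n/a").
#' @export
patty_formulations <- function() {
  p1 <- data.frame(
    category  = "P1",
    treatment = paste0("fat_", c(0, 2.5, 5, 7.5, 10, 15, 20, 25, 30, 40)),
    tm_percent = NA_real_, tme_percent = NA_real_,
    authenticity = "authentic"
  )
  p2 <- data.frame(
    category  = "P2",
    treatment = c("beef_control",
                  "pork_1", "pork_2", "pork_3",
                  "lamb_1", "lamb_2", "lamb_3",
                  "ostrich_1", "ostrich_2", "ostrich_3"),
    tm_percent = NA_real_, tme_percent = NA_real_,
    # level-3 substitutions (33.75%) exceed the 25% other-species allowance
    authenticity = c("authentic",
                     "authentic", "authentic", "adulterated",
                     "authentic", "authentic", "adulterated",
                     "authentic", "authentic", "adulterated")
  )
  p3 <- data.frame(
    category  = "P3",
    treatment = paste0("TM_", c(45, 55, 60, 70, 80)),
    tm_percent  = c(45, 55, 60, 70, 80),
    tme_percent = c(55.8, 67, 70, 85, 82.4),
    authenticity = c("adulterated", "authentic", "authentic",
                     "authentic", "authentic")
  )
  # treatments labelled by the published TM% row values
  p4 <- data.frame(
    category  = "P4",
    treatment = paste0("TM_", c(0, 20, 25, 35, 40)),
    tm_percent  = c(0, 20, 25, 35, 40),
    tme_percent = c(55, 55, 45, 63, 67.3),
    authenticity = c("adulterated", "adulterated", "adulterated",
                     "authentic", "authentic")
  )
  out <- rbind(p1, p2, p3, p4)
  out$category <- factor(out$category, levels = patty_categories())
  out
}

#' The four patty category labels, in regulatory order
#' @return Character vector `c("P1","P2","P3","P4")`.
#' @export
patty_categories <- function() c("P1", "P2", "P3", "P4")

#' Published mean proximate composition per patty category
#'
#' Category-level means of the wet-lab proximate analysis (mass fractions).
#' The carbohydrate/filler fraction is the remainder to unity, floored at
#' zero: P1's published moisture + fat + protein means total 100.8%, a
#' rounding artefact of the published table that the package preserves
#' rather than rescales.
#'
#' @return A 4 x 4 matrix (rows P1-P4; columns moisture, fat, protein,
#'   filler) of mass fractions.
#' @export
category_composition_means <- function() {
  m <- rbind(
    P1 = c(moisture = 0.645, fat = 0.168, protein = 0.195),
    P2 = c(moisture = 0.650, fat = 0.119, protein = 0.144),
    P3 = c(moisture = 0.640, fat = 0.116, protein = 0.142),
    P4 = c(moisture = 0.650, fat = 0.124, protein = 0.104)
  )
  cbind(m, filler = pmax(0, 1 - rowSums(m)))
}

#' Draw a proximate composition for one patty
#'
#' In `"category_mean"` mode the patty composition is the published category
#' mean, shifted by a small deterministic per-treatment offset (at most
#' +/- 1 absolute percentage point, so treatments within a category differ
#' but stay within class) and perturbed by random per-patty jitter. The
#' jitter is multiplicative with total relative standard deviation
#' `jitter_sd`, decomposed into a component shared across constituents
#' (correlation `jitter_cor`, modelling batch-level density/moisture
#' variation between patties pressed from one batter) and an independent
#' per-constituent component. In `"formulation_linear"` mode the composition
#' is the ingredient-fraction-weighted mix of a documented default
#' ingredient nutrient table; over many draws both modes average to the
#' category mean.
#'
#' @param category One of `"P1"`..`"P4"`.
#' @param treatment Treatment label from [patty_formulations()]; `NULL`
#'   means no treatment offset.
#' @param mode `"category_mean"` (default) or `"formulation_linear"`.
#' @param jitter_sd Relative standard deviation of per-patty jitter
#'   (default 0.05).
#' @param jitter_cor Correlation of jitter across constituents (default 0.9).
#' @return Named numeric vector (moisture, fat, protein, filler) of mass
#'   fractions, class `composition_profile`.
#' @export
composition_for <- function(category, treatment = NULL,
                            mode = c("category_mean", "formulation_linear"),
                            jitter_sd = 0.05, jitter_cor = 0.9) {
  mode <- match.arg(mode)
  if (!category %in% patty_categories())
    stop(sprintf("unknown patty category '%s'", category), call. = FALSE)
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)

  base <- switch(mode,
    category_mean      = category_composition_means()[category, ],
    formulation_linear = linear_mix_composition(category, treatment)
  )
  if (mode == "category_mean")
    base <- base + treatment_offset(category, treatment)

  if (jitter_sd > 0) {
    rho <- jitter_cor
    z_common <- stats::rnorm(1)
    z_indiv  <- stats::rnorm(length(base))
    rel <- jitter_sd * (rho * z_common + sqrt(1 - rho^2) * z_indiv)
    base <- base * (1 + rel)
  }
  out <- pmin(pmax(base, 0), 1)
  class(out) <- c("composition_profile", class(out))
  out
}

# Deterministic within-category treatment offsets, capped at 1 absolute
# percentage point. Treatments mostly manipulate added fat (P1), substituted
# lean species (P2) or water/extender balance (P3/P4); a signed linear ramp
# over the treatment index on the fat/moisture/protein axes reproduces
# ordered within-class structure without touching the filler fraction that
# separates the categories.
treatment_offset <- function(category, treatment) {
  zero <- c(moisture = 0, fat = 0, protein = 0, filler = 0)
  if (is.null(treatment)) return(zero)
  form <- patty_formulations()
  labs <- form$treatment[form$category == category]
  j <- match(treatment, labs)
  if (is.na(j))
    stop(sprintf("unknown treatment '%s' for category %s", treatment,
                 category), call. = FALSE)
  n <- length(labs)
  u <- if (n == 1L) 0 else (j - (n + 1) / 2) / ((n - 1) / 2)  # in [-1, 1]
  c(moisture = -0.007, fat = 0.01, protein = -0.003, filler = 0) * u
}

# Default per-ingredient nutrient table (mass fractions) used by the
# formulation_linear mode: typical composition of the lean meats, fats and
# extenders in the recipes. Values chosen so ingredient-weighted mixes of
# the published recipes sit near the category means.
ingredient_nutrients <- function() {
  rbind(                 # moisture   fat  protein filler
    lean_meat   = c(0.72, 0.06, 0.215, 0.005),
    beef_fat    = c(0.18, 0.78, 0.040, 0.000),
    mrm         = c(0.68, 0.14, 0.150, 0.030),
    spice_pack  = c(0.10, 0.02, 0.080, 0.800),
    water       = c(1.00, 0.00, 0.000, 0.000),
    burger_rusk = c(0.08, 0.02, 0.100, 0.800),
    tvp         = c(0.08, 0.01, 0.500, 0.410),
    soya_fibre  = c(0.08, 0.01, 0.150, 0.760)
  )
}

# Recipe rows (ingredient mass %) for the linear mixing mode, transcribed
# from the published formulation tables.
formulation_recipes <- function() {
  list(
    P1 = local({
      fat <- c(0, 2.5, 5, 7.5, 10, 15, 20, 25, 30, 40)
      r <- lapply(fat, function(f) c(lean_meat = 100 - f, beef_fat = f))
      names(r) <- paste0("fat_", fat)
      r
    }),
    P2 = local({
      lev <- c(beef_control = 0, pork_1 = 18.75, pork_2 = 7.5, pork_3 = 33.75,
               lamb_1 = 18.75, lamb_2 = 7.5, lamb_3 = 33.75,
               ostrich_1 = 18.75, ostrich_2 = 7.5, ostrich_3 = 33.75)
      r <- lapply(lev, function(s)
        c(lean_meat = 65, beef_fat = 10, spice_pack = 10, water = 15))
      # substituted species share the lean-meat nutrient profile
      r
    }),
    P3 = list(
      TM_45 = c(lean_meat = 35, beef_fat = 10, spice_pack = 10, water = 35.5,
                burger_rusk = 5, tvp = 4.5),
      TM_55 = c(lean_meat = 45, beef_fat = 10, spice_pack = 10, water = 30,
                tvp = 5),
      TM_60 = c(lean_meat = 50, beef_fat = 10, spice_pack = 10, water = 25.5,
                tvp = 4.5),
      TM_70 = c(lean_meat = 60, beef_fat = 10, spice_pack = 10, water = 13.75,
                tvp = 6.25),
      TM_80 = c(lean_meat = 70, beef_fat = 10, spice_pack = 10, water = 9,
                tvp = 1)
    ),
    P4 = list(
      TM_0  = c(mrm = 50, spice_pack = 10, water = 35, tvp = 5),
      TM_20 = c(mrm = 30.2, lean_meat = 10, beef_fat = 10, spice_pack = 10,
                water = 33.8, soya_fibre = 1, tvp = 5),
      TM_25 = c(mrm = 15.8, lean_meat = 15, beef_fat = 10, spice_pack = 10,
                water = 41.2, soya_fibre = 1, burger_rusk = 2, tvp = 5),
      TM_35 = c(mrm = 21, lean_meat = 25, beef_fat = 10, spice_pack = 10,
                water = 29, tvp = 5),
      TM_40 = c(mrm = 21, lean_meat = 30, beef_fat = 10, spice_pack = 10,
                water = 24, tvp = 5)
    )
  )
}

linear_mix_composition <- function(category, treatment) {
  recipes <- formulation_recipes()[[category]]
  if (is.null(treatment)) treatment <- names(recipes)[1L]
  rec <- recipes[[treatment]]
  if (is.null(rec))
    stop(sprintf("unknown treatment '%s' for category %s", treatment,
                 category), call. = FALSE)
  if (abs(sum(rec) - 100) > 1e-6)
    stop("ingredient fractions must sum to 100", call. = FALSE)
  nut <- ingredient_nutrients()
  mix <- drop(crossprod(rec[names(rec)] / 100, nut[names(rec), , drop = FALSE]))
  names(mix) <- c("moisture", "fat", "protein", "filler")
  mix
}
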