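#' Construct a steady-state chemostat record
#'
#' One steady-state sample of a chemostat culture: dilution rate, working
#' volume, substrate in the feed and in the effluent, product concentrations
#' and the cell-pellet elemental composition.  At steady state the specific
#' growth rate equals the dilution rate, so volumetric production rates
#' follow directly from concentrations (see [volumetric_flux()]).
#'
#' @param strain_id strain identifier.
#' @param D dilution rate, 1/h (default 0.1 as used for carbon-limited
#'   cellobiose chemostats).
#' @param V working volume, L (default 0.3).
#' @param feed_substrate substrate concentration in the feed, g/L.
#' @param residual_substrate residual substrate in the vessel, g/L.
#' @param products named numeric vector of product concentrations, mM.
#' @param pellet_C,pellet_N pellet carbon and nitrogen, g/L.
#' @return An object of class `"chemostat_record"`.
#' @export
chemostat_record <- function(strain_id, D = 0.1, V = 0.3,
                             feed_substrate = 5, residual_substrate = 0,
                             products = numeric(0),
                             pellet_C = 0, pellet_N = 0) {
  stopifnot(D > 0, V > 0,
            residual_substrate <= feed_substrate,
            residual_substrate >= 0,
            all(products >= 0), pellet_C >= 0, pellet_N >= 0)
  if (length(products) && is.null(names(products)))
    stop("'products' must be a named vector (mM)")
  structure(list(strain_id = strain_id, D = D, V = V,
                 feed_substrate = feed_substrate,
                 residual_substrate = residual_substrate,
                 products = products,
                 pellet_C = pellet_C, pellet_N = pellet_N),
            class = "chemostat_record")
}

#' @export
print.chemostat_record <- function(x, ...) {
  cat("Chemostat record:", x$strain_id,
      sprintf("(D = %.3g 1/h, V = %.3g L, feed %.3g g/L)\n",
              x$D, x$V, x$feed_substrate))
  if (length(x$products)) {
    cat("  products (mM):",
        paste(sprintf("%s %.3g", names(x$products), x$products),
              collapse = ", "), "\n")
  }
  cat(sprintf("  pellet C %.3g g/L, pellet N %.3g g/L\n",
              x$pellet_C, x$pellet_N))
  invisible(x)
}

#' Volumetric product flux of a chemostat at steady state
#'
#' At steady state the production rate of a product equals dilution rate x
#' concentration x working volume (q = D C V), in mmol/h per reactor.
#' Multiplying by the product's carbon count gives the carbon flux in
#' mmol C-atoms/h, the unit used for flux clustering.
#'
#' @param record a [chemostat_record()].
#' @param product product name (must be present in `record$products` and in
#'   the registry).
#' @param registry metabolite registry, see [metabolite_registry()].
#' @param per_liter if `TRUE`, report per-liter rates (mmol/L/h) instead of
#'   per-reactor rates.
#' @return Named numeric of length 2: `molar` (mmol/h) and `carbon`
#'   (mmol C/h).
#' @examples
#' r <- chemostat_record("wt", D = 0.1, V = 0.3, products = c(ethanol = 20))
#' volumetric_flux(r, "ethanol")  # 0.6 mmol/h, 1.2 mmol C/h
#' @export
volumetric_flux <- function(record, product,
                            registry = metabolite_registry(),
                            per_liter = FALSE) {
  stopifnot(inherits(record, "chemostat_record"))
  key <- normalize_species(product)
  have <- normalize_species(names(record$products))
  i <- match(key, have)
  if (is.na(i)) stop("product not measured in record: ", product)
  spec <- met_lookup(product, registry)
  vol <- if (per_liter) 1 else record$V
  molar <- record$D * record$products[[i]] * vol
  c(molar = molar, carbon = molar * spec$n_carbon)
}

#' Carbon flux profile of a chemostat record
#'
#' Computes the per-product carbon flux (mmol C-atoms/h) for every measured
#' product plus the cell-pellet carbon stream (pellet carbon g/L x D x V /
#' 12 g/mol x 1000), and the fraction of the total carbon flux carried by
#' each stream.
#'
#' @inheritParams volumetric_flux
#' @param include_pellet include the pellet carbon stream (default `TRUE`).
#' @return An object of class `"flux_profile"`: list with `strain_id`,
#'   `molar` (mmol/h), `carbon` (mmol C/h), `fractions` and `total_carbon`.
#' @export
carbon_flux_profile <- function(record, registry = metabolite_registry(),
                                include_pellet = TRUE, per_liter = FALSE) {
  stopifnot(inherits(record, "chemostat_record"))
  prods <- names(record$products)
  fl <- vapply(prods, function(p)
    volumetric_flux(record, p, registry, per_liter), numeric(2))
  molar <- if (length(prods)) fl["molar", ] else numeric(0)
  carbon <- if (length(prods)) fl["carbon", ] else numeric(0)
  names(molar) <- names(carbon) <- prods
  if (include_pellet) {
    vol <- if (per_liter) 1 else record$V
    pellet_flux <- record$pellet_C * record$D * vol / 12.011 * 1000
    carbon <- c(carbon, pellet_carbon = pellet_flux)
  }
  total <- sum(carbon)
  if (total <= 0) stop("total carbon flux is zero for strain ",
                       record$strain_id)
  structure(list(strain_id = record$strain_id, molar = molar,
                 carbon = carbon, fractions = carbon / total,
                 total_carbon = total),
            class = "flux_profile")
}

#' @export
print.flux_profile <- function(x, ...) {
  cat("Carbon flux profile:", x$strain_id,
      sprintf("(total %.3g mmol C/h)\n", x$total_carbon))
  df <- data.frame(carbon_flux = round(x$carbon, 4),
                   fraction = round(x$fractions, 4))
  print(df)
  invisible(x)
}

#' Strains-by-products carbon flux matrix
#'
#' Builds the matrix used for fermentation phenotype clustering from a list
#' of chemostat records, averaging replicate records of the same strain.
#'
#' @param records list of [chemostat_record()] objects.
#' @inheritParams carbon_flux_profile
#' @return Numeric matrix, strains (rows, sorted by id) x carbon streams
#'   (columns), in mmol C-atoms/h.
#' @export
carbon_flux_matrix <- function(records, registry = metabolite_registry(),
                               include_pellet = TRUE, per_liter = FALSE) {
  stopifnot(length(records) > 0)
  profs <- lapply(records, carbon_flux_profile, registry = registry,
                  include_pellet = include_pellet, per_liter = per_liter)
  cols <- unique(unlist(lapply(profs, function(p) names(p$carbon))))
  strains <- sort(unique(vapply(profs, `[[`, "", "strain_id")))
  m <- matrix(0, length(strains), length(cols),
              dimnames = list(strains, cols))
  n <- setNames(integer(length(strains)), strains)
  for (p in profs) {
    m[p$strain_id, names(p$carbon)] <- m[p$strain_id, names(p$carbon)] +
      p$carbon
    n[p$strain_id] <- n[p$strain_id] + 1L
  }
  sweep(m, 1, n, "/")
}

#' Carbon recovery of a fermentation
#'
#' Percentage of consumed substrate carbon accounted for by measured
#' products, cell-pellet carbon and, optionally, the CO2 stoichiometrically
#' inferred from the products' formation pathways (via the registry's
#' `co2_coeff`; CO2 is rarely measured directly in these fermentations).
#'
#' @param substrate_C_consumed consumed substrate carbon, mol C.
#' @param products named numeric vector of product amounts, mol.
#' @param pellet_C cell pellet carbon, mol C.
#' @param include_co2 add inferred CO2 to the accounted carbon
#'   (default `TRUE`).
#' @param registry metabolite registry.
#' @return Carbon recovery in percent.
#' @export
carbon_recovery <- function(substrate_C_consumed, products, pellet_C = 0,
                            include_co2 = TRUE,
                            registry = metabolite_registry()) {
  if (substrate_C_consumed <= 0) stop("substrate carbon consumed must be > 0")
  spec <- met_lookup(names(products), registry)
  accounted <- sum(products * spec$n_carbon) + pellet_C
  if (include_co2) accounted <- accounted + sum(products * spec$co2_coeff)
  100 * accounted / substrate_C_consumed
}

#' Pellet carbon to nitrogen mass ratio
#'
#' Element-wise ratio of pellet carbon to pellet nitrogen (g C/g N), the
#' biomass composition proxy that stays constant across strains and
#' substrate loadings.
#'
#' @param pellet_C,pellet_N pellet carbon and nitrogen, g/L (vectorised).
#' @return g C / g N, numeric.
#' @seealso [cn_slope()] for the regression estimate over a record set.
#' @export
cn_ratio <- function(pellet_C, pellet_N) {
  if (any(pellet_N <= 0)) stop("pellet nitrogen must be > 0")
  pellet_C / pellet_N
}

#' Regression slope of pellet carbon on pellet nitrogen
#'
#' Least-squares regression of pellet carbon (g/L) on pellet nitrogen (g/L)
#' across a set of steady-state measurements; the slope estimates the
#' biomass C:N mass ratio.  Because both quantities vanish together with
#' biomass, the ratio is a proportionality through the origin and the
#' regression is fitted without an intercept by default; set
#' `intercept = TRUE` for an ordinary intercept fit.
#'
#' @param pellet_C,pellet_N pellet carbon and nitrogen, g/L.
#' @param intercept include an intercept (default `FALSE`: line through the
#'   origin).
#' @return List with `slope`, `se`, and the fitted `lm` object.
#' @export
cn_slope <- function(pellet_C, pellet_N, intercept = FALSE) {
  stopifnot(length(pellet_C) == length(pellet_N), length(pellet_C) >= 3)
  fit <- if (intercept) lm(pellet_C ~ pellet_N) else lm(pellet_C ~ pellet_N - 1)
  dof <- length(pellet_C) - length(coef(fit))
  s2 <- sum(residuals(fit)^2) / dof
  ssx <- if (intercept) sum((pellet_N - mean(pellet_N))^2)
         else sum(pellet_N^2)
  list(slope = unname(coef(fit)[["pellet_N"]]),
       se = sqrt(s2 / ssx),
       fit = fit)
}

#' Ethanol yield as percent of the theoretical maximum
#'
#' The theoretical maximum is 4 mol ethanol per mol cellobiose (2 per
#' hexose unit); pass `max_per_substrate = 2` for glucose-equivalent
#' substrate amounts.
#'
#' @param ethanol ethanol produced, mol (or mmol, any consistent unit).
#' @param substrate_consumed substrate consumed, mol (same unit basis).
#' @param max_per_substrate mol ethanol per mol substrate at the theoretical
#'   maximum (default 4, cellobiose basis).
#' @return Percent of theoretical maximum yield.
#' @examples
#' theoretical_ethanol_yield(1.8, 1)  # 45
#' @export
theoretical_ethanol_yield <- function(ethanol, substrate_consumed,
                                      max_per_substrate = 4) {
  if (any(substrate_consumed <= 0)) stop("substrate consumed must be > 0")
  100 * ethanol / (max_per_substrate * substrate_consumed)
}

#' Maximum specific growth rate from an OD time series
#'
#' Scans every contiguous window of at least `min_points` points for
#' log-linearity (coefficient of determination >= `min_r2`) and reports the
#' steepest qualifying slope as the maximum specific growth rate -- the
#' window bounded to the exponential phase rather than diluted by the
#' transition into stationary phase.  Among equal slopes the longest window
#' wins.  If no window qualifies the fit is reported as failed rather than
#' returning a number.
#'
#' @param time time points, h.
#' @param od OD600 readings (> 0).
#' @param min_points minimum window size (default 5).
#' @param min_r2 minimum R-squared for a window to count as log-linear
#'   (default 0.99).
#' @return Object of class `"growth_fit"`: list with `converged`, `mu_max`
#'   (1/h, `NA` on failure), `window` (index range), `r_squared`, `message`.
#' @examples
#' t <- 0:10
#' fit <- growth_rate_fit(t, 0.01 * exp(0.3 * t))
#' fit$mu_max  # 0.3
#' @export
growth_rate_fit <- function(time, od, min_points = 5, min_r2 = 0.99) {
  stopifnot(length(time) == length(od))
  if (length(time) < min_points)
    stop("need at least ", min_points, " points")
  if (any(od <= 0)) stop("OD values must be > 0")
  o <- order(time)
  time <- time[o]; od <- od[o]
  ly <- log(od)
  n <- length(time)
  best <- NULL
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      tt <- time[i:j]; yy <- ly[i:j]
      if (var(yy) == 0) next   # flat: not growth
      fit <- lm(yy ~ tt)
      r2 <- 1 - sum(residuals(fit)^2) / sum((yy - mean(yy))^2)
      if (is.na(r2) || r2 < min_r2) next
      len <- j - i + 1
      slope <- unname(coef(fit)[2])
      if (is.null(best) || slope > best$slope + 1e-12 ||
          (abs(slope - best$slope) <= 1e-12 && len > best$len)) {
        best <- list(len = len, r2 = r2, i = i, j = j, slope = slope)
      }
    }
  }
  if (is.null(best)) {
    out <- list(converged = FALSE, mu_max = NA_real_, window = NULL,
                r_squared = NA_real_,
                message = sprintf(
                  "no window of >= %d points with R^2 >= %g found",
                  min_points, min_r2))
  } else {
    out <- list(converged = TRUE, mu_max = best$slope,
                window = c(best$i, best$j), r_squared = best$r2,
                message = "ok")
  }
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Log-linear growth fit: mu_max = %.4g 1/h (points %d-%d, R^2 = %.4f)\n",
      x$mu_max, x$window[1], x$window[2], x$r_squared))
  } else {
    cat("Growth rate fit failed:", x$message, "\n")
  }
  invisible(x)
}
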