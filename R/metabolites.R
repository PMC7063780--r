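#' Built-in metabolite registry
#'
#' Registry of the metabolites handled by the flux accounting functions.
#' Each entry carries the number of carbon atoms per molecule, the molar
#' mass, the degree of reduction (available electrons per molecule,
#' gamma = 4C + H - 2O - 3N with ammonia-level nitrogen), and the number of
#' moles of CO2 stoichiometrically co-produced per mole of product during
#' fermentative formation from sugar.  The CO2 coefficients encode the usual
#' pyruvate-node stoichiometry: one CO2 per acetyl-CoA-derived product
#' (ethanol, acetate), two per isobutanol (two decarboxylations), one per
#' 2,3-butanediol and one per valine; glycolytic products (lactate,
#' pyruvate, formate) and the remaining amino acids carry none.
#'
#' The two-electron carriers NADH and reduced ferredoxin are included so
#' fermentation equations can be balanced for electrons; they carry no
#' carbon.
#'
#' @return A data.frame with columns `name`, `n_carbon`, `molar_mass`,
#'   `degree_of_reduction`, `co2_coeff`.
#' @examples
#' reg <- metabolite_registry()
#' reg[reg$name == "ethanol", ]
#' @export
metabolite_registry <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name          n_carbon molar_mass degree_of_reduction co2_coeff
cellobiose    12       342.30     48                  0
glucose       6        180.16     24                  0
ethanol       2        46.07      12                  1
acetate       2        60.05      8                   1
lactate       3        90.08      12                  0
formate       1        46.03      2                   0
pyruvate      3        88.06      10                  0
malate        4        134.09     12                  0
fumarate      4        116.07     12                  0
isobutanol    4        74.12      24                  2
butanediol    4        90.12      22                  1
valine        5        117.15     24                  1
alanine       3        89.09      12                  0
isoleucine    6        131.17     30                  0
glutamine     5        146.14     18                  0
glutamate     5        147.13     18                  0
pyroglutamate 5        129.11     18                  0
co2           1        44.01      0                   0
h2            0        2.016      2                   0
nadh          0        0          2                   0
fd_red        0        0          2                   0
")
  df
}

# canonical species spelling: lower case, separators collapsed, a few aliases
normalize_species <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("[ ,'-]", "_", y)
  y <- gsub("_+", "_", y)
  y <- gsub("^_|_$", "", y)
  alias <- c(
    "2_3_butanediol" = "butanediol", "23_butanediol" = "butanediol",
    "2_3_bdo" = "butanediol",
    "fdred" = "fd_red", "fd" = "fd_red", "ferredoxin" = "fd_red",
    "hydrogen" = "h2", "carbon_dioxide" = "co2",
    "glutamic_acid" = "glutamate"
  )
  hit <- alias[y]
  ifelse(is.na(hit), y, hit)
}

#' Look up metabolites in a registry
#'
#' @param names character vector of metabolite names (case and punctuation
#'   insensitive; "2,3-butanediol" and "Fd_red" style spellings accepted).
#' @param registry a registry data.frame, see [metabolite_registry()].
#' @return The matching registry rows, in the order of `names`.
#' @export
met_lookup <- function(names, registry = metabolite_registry()) {
  key <- normalize_species(names)
  idx <- match(key, registry$name)
  if (anyNA(idx)) {
    stop("unknown metabolite(s): ",
         paste(unique(names[is.na(idx)]), collapse = ", "))
  }
  registry[idx, , drop = FALSE]
}

#' Parse a fermentation equation
#'
#' Parses text such as `"glucose -> 2 acetate + 2 CO2 + 2 NADH + 2 Fd_red"`
#' into a stoichiometry usable by [electron_balance()].  Coefficients default
#' to 1; `->` or `=` separates reactants from products.
#'
#' @param text reaction string.
#' @return A list with named numeric vectors `reactants` and `products`
#'   (names are canonical registry species), class `"stoichiometry"`.
#' @examples
#' parse_reaction("glucose -> 2 ethanol + 2 CO2")
#' @export
parse_reaction <- function(text) {
  sides <- strsplit(text, "->|=>|=", perl = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction must have one '->' separator")
  parse_side <- function(s) {
    terms <- strsplit(s, "\\+")[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    coefs <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+)\\s+(.+)$", tm))[[1]]
      if (length(m) == 3L) {
        coef <- as.numeric(m[2])
        sp <- normalize_species(m[3])
      } else {
        coef <- 1
        sp <- normalize_species(tm)
      }
      coefs[sp] <- coef + ifelse(is.na(coefs[sp]), 0, coefs[sp])
    }
    coefs
  }
  out <- list(reactants = parse_side(sides[1]), products = parse_side(sides[2]))
  class(out) <- "stoichiometry"
  out
}

#' Electron balance of a fermentation equation
#'
#' Residual available electrons per mole of substrate: the summed degree of
#' reduction of the products minus that of the reactants.  Zero means the
#' equation is balanced for electrons; a negative residual means the written
#' products are more oxidised than the substrate, so a reduced co-product
#' (NADH, reduced ferredoxin, H2, ...) is required to close the balance.
#'
#' For example the acetate pathway written as glucose to 2 acetate + 2 CO2 is
#' short 8 electrons, which is exactly closed by co-producing 2 NADH and 2
#' reduced ferredoxin.
#'
#' @param rxn a `"stoichiometry"` object from [parse_reaction()], or a
#'   reaction string (parsed on the fly).
#' @param registry metabolite registry, see [metabolite_registry()].
#' @return Residual electrons (numeric scalar).
#' @examples
#' electron_balance("glucose -> 2 ethanol + 2 CO2")     # 0
#' electron_balance("glucose -> 2 acetate + 2 CO2")     # -8
#' @export
electron_balance <- function(rxn, registry = metabolite_registry()) {
  if (is.character(rxn)) rxn <- parse_reaction(rxn)
  stopifnot(inherits(rxn, "stoichiometry"))
  side_e <- function(v) {
    if (length(v) == 0L) return(0)
    sum(v * met_lookup(names(v), registry)$degree_of_reduction)
  }
  side_e(rxn$products) - side_e(rxn$reactants)
}
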