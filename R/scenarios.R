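#' Built-in fate scenarios
#'
#' Two bracketing parameter sets for aqueous photochemistry, both with the
#' same volatilization and gas-phase constants:
#'
#' * `"fast"` — shallow (1 m), low-DOC water with high nitrate/nitrite,
#'   hence intense aqueous photochemistry:
#'   `k_d = 0.3`, `k_f = 0.05`, `k_d_prime = 0.4` day-1.
#' * `"slow"` — deep (10 m), high-DOC water with low nitrate/nitrite:
#'   `k_d = 0.02`, `k_f = 0.005`, `k_d_prime = 0.03` day-1.
#'
#' Both use `k_vol = 0.052` day-1 (two-film volatilization estimate at calm
#' wind) and `k_g = 0.46` day-1 (the gas-phase OH pseudo-first-order
#' constant from the measured second-order rate constant at the 24 h
#' average OH level). `k_g` is an ordinary scenario field: override it to
#' explore other OH regimes.
#'
#' Alternatively, `name` may be a path to a YAML file with keys `k_d`,
#' `k_f`, `k_d_prime`, `k_vol`, `k_g` (all day-1) and an optional
#' `pathway_split` block with keys `k_OH_w`, `k_3CDOM`, `k_dp`.
#'
#' @param name `"fast"`, `"slow"`, or a path to a YAML scenario file.
#' @return A [fate_scenario()].
#' @examples
#' load_scenario("fast")
#' @export
load_scenario <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  builtin <- list(
    fast = list(k_d = 0.3, k_f = 0.05, k_d_prime = 0.4,
                k_vol = 0.052, k_g = 0.46),
    slow = list(k_d = 0.02, k_f = 0.005, k_d_prime = 0.03,
                k_vol = 0.052, k_g = 0.46)
  )
  if (name %in% names(builtin)) {
    p <- builtin[[name]]
  } else if (file.exists(name)) {
    p <- yaml::read_yaml(name)
    need <- c("k_d", "k_f", "k_d_prime", "k_vol", "k_g")
    miss <- setdiff(need, names(p))
    if (length(miss))
      stop("scenario file '", name, "' is missing keys: ",
           paste(miss, collapse = ", "))
  } else {
    stop("unknown scenario '", name, "'; available built-ins: ",
         paste(names(builtin), collapse = ", "),
         " (or give a path to a YAML scenario file)")
  }
  fate_scenario(k_d = p$k_d, k_f = p$k_f, k_d_prime = p$k_d_prime,
                k_vol = p$k_vol, k_g = p$k_g,
                pathway_split = p$pathway_split)
}

#' Write a fate scenario to a YAML file
#'
#' Serializes a scenario so that [load_scenario()] reads it back
#' identically (full double precision is preserved).
#'
#' @param s A [fate_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(s, path) {
  stopifnot(inherits(s, "fate_scenario"))
  p <- list(k_d = s$k_d, k_f = s$k_f, k_d_prime = s$k_d_prime,
            k_vol = s$k_vol, k_g = s$k_g)
  if (!is.null(s$pathway_split)) p$pathway_split <- as.list(s$pathway_split)
  yaml::write_yaml(p, path, precision = 17)
  invisible(path)
}

#' IBAP formation yield with plausibility range
#'
#' Computes the formation yield `f = k_f / k_d` and flags whether it lies
#' in the 0.18-0.26 range that aqueous photochemical modeling predicts for
#' the IBP -> IBAP conversion across environmental conditions. The check
#' is informational: the fast scenario's yield (0.167) sits slightly below
#' the range because its rounded rate constants were chosen as bracketing
#' values, not as a consistent model output.
#'
#' @param s A [fate_scenario()] with `k_d > 0`.
#' @param range Numeric length-2 plausibility interval (default
#'   `c(0.18, 0.26)`).
#' @return A list with `f` and logical `within_range`.
#' @export
yield_range_check <- function(s, range = c(0.18, 0.26)) {
  stopifnot(inherits(s, "fate_scenario"))
  if (s$k_d <= 0) stop("'k_d' must be > 0")
  f <- s$k_f / s$k_d
  list(f = f, within_range = f >= range[1] && f <= range[2])
}

#' Aqueous photoreactivity reference parameters
#'
#' Second-order rate constants toward the photochemically produced
#' reactive intermediates of sunlit surface waters, direct-photolysis
#' quantum yields, and IBP -> IBAP formation yields, for ibuprofen (IBP)
#' and 4-isobutylacetophenone (IBAP). These are the inputs a surface-water
#' photochemistry model needs to produce the `k_d`, `k_f`, `k_d_prime`
#' scenario constants; they are shipped here as citable reference data
#' (no photochemical radiative-transfer model is included in this
#' package).
#'
#' @return A data frame with columns `parameter`, `units`, `IBP`, `IBAP`.
#'   `phi_dp` is the direct-photolysis quantum yield (mol Einstein-1);
#'   `k_oh_aq`, `k_1o2`, `k_3cdom` are second-order rate constants
#'   (M-1 s-1) toward aqueous OH, singlet oxygen and excited triplet
#'   CDOM; the `eta_*` rows are IBAP formation yields from IBP through
#'   each pathway (dimensionless; IBAP column `NA` — they describe the
#'   IBP -> IBAP conversion; the singlet-oxygen channel is negligible).
#' @export
photoreactivity_params <- function() {
  data.frame(
    parameter = c("phi_dp", "k_oh_aq", "k_1o2", "k_3cdom",
                  "eta_dp", "eta_oh", "eta_1o2", "eta_3cdom"),
    units = c("mol Einstein-1", "M-1 s-1", "M-1 s-1", "M-1 s-1",
              "dimensionless", "dimensionless", "dimensionless",
              "dimensionless"),
    IBP  = c(0.33, 1.0e10, 6.0e4, 1.5e9, 0.25, 0.023, 0, 0.31),
    IBAP = c(5.0e-2, 2.0e10, 2.3e6, 3.2e9, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}
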