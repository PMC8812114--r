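# Pinned isotope masses (AME2020-consistent IUPAC values) and isotopic
# abundances, plus 2021 standard atomic weights. Pinned here, not looked up at
# run time, so every derived number in the package is bit-stable.
#
# "D" is deuterium treated as isotopically pure 2H and "[13C]" as pure 13C:
# isotope-labelled internal standards (e.g. ciprofloxacin-d8,
# azithromycin-13Cd3) are nominally fully labelled at those positions.

.ISOTOPES <- list(
  H  = list(mass = c(1.0078250319, 2.0141017781), abund = c(0.999885, 0.000115)),
  D  = list(mass = 2.0141017781, abund = 1),
  C  = list(mass = c(12.0, 13.0033548351), abund = c(0.9893, 0.0107)),
  `[13C]` = list(mass = 13.0033548351, abund = 1),
  N  = list(mass = c(14.0030740044, 15.0001088989), abund = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
            abund = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
            abund = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(mass = 30.9737619984, abund = 1),
  F  = list(mass = 18.9984031627, abund = 1),
  Cl = list(mass = c(34.9688526820, 36.9659026020), abund = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183376000, 80.9162897000), abund = c(0.5069, 0.4931)),
  I  = list(mass = 126.9044719000, abund = 1),
  Na = list(mass = 22.9897692820, abund = 1),
  K  = list(mass = c(38.9637064864, 39.9639981660, 40.9618252579),
            abund = c(0.932581, 0.000117, 0.067302))
)

# 2021 IUPAC standard atomic weights (conventional values for interval
# elements); labelled species use their pure-isotope mass.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, D = 2.0141017781, C = 12.011, `[13C]` = 13.0033548351,
  N = 14.007, O = 15.999, S = 32.06, P = 30.973761998, F = 18.998403163,
  Cl = 35.45, Br = 79.904, I = 126.90447, Na = 22.98976928, K = 39.0983
)

.PROTON_MASS <- 1.00727646677
.ELECTRON_MASS <- 0.00054857990907

# Canonical element order for serialization: Hill convention (C, H first),
# with labelled species immediately after their parent element.
.HILL_ORDER <- c("C", "[13C]", "H", "D",
                 sort(setdiff(names(.ISOTOPES), c("C", "[13C]", "H", "D"))))

#' Supported adducts
#'
#' Returns the built-in adduct table used by [adduct_mz()]. Each row gives the
#' neutral-mass offset (Da) and charge sign of a singly charged adduct.
#'
#' @return A data.frame with columns `adduct`, `delta_mass`, `charge_sign`.
#' @export
adduct_table <- function() {
  data.frame(
    adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+", "[M-H]-", "[M+Cl]-"),
    delta_mass = c(
      .PROTON_MASS,
      22.9897692820 - .ELECTRON_MASS,
      18.0338254 ,  # NH4+ (N + 4H - e)
      38.9637064864 - .ELECTRON_MASS,
      -.PROTON_MASS,
      34.9688526820 + .ELECTRON_MASS
    ),
    charge_sign = c(1L, 1L, 1L, 1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
}
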