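# Element isotope table: natural isotopic masses (u) and abundances.
#
# Biochemically common elements (CHNOPS, halogens, alkali/alkaline and first
# row transition metals) carry their full natural isotope distributions.
# Exotic elements that appear only in the implausible decoy-adduct universe
# carry their principal isotope; a decoy ion's pattern is then dominated by
# the molecule's own C/H/N/O/S envelope, which is what matters for scoring.

.isotope_data <- local({
  e <- list(
    H  = list(mass = c(1.00782503207, 2.01410177785), abundance = c(0.999885, 0.000115)),
    C  = list(mass = c(12.0, 13.0033548378),          abundance = c(0.9893, 0.0107)),
    N  = list(mass = c(14.0030740048, 15.0001088982), abundance = c(0.99636, 0.00364)),
    O  = list(mass = c(15.9949146196, 16.99913170, 17.9991610),
              abundance = c(0.99757, 0.00038, 0.00205)),
    P  = list(mass = 30.97376163, abundance = 1),
    S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
              abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
    Na = list(mass = 22.9897692809, abundance = 1),
    K  = list(mass = c(38.96370668, 39.96399848, 40.96182576),
              abundance = c(0.932581, 0.000117, 0.067302)),
    F  = list(mass = 18.99840322, abundance = 1),
    Cl = list(mass = c(34.96885268, 36.96590259), abundance = c(0.7576, 0.2424)),
    Br = list(mass = c(78.9183371, 80.9162906), abundance = c(0.5069, 0.4931)),
    I  = list(mass = 126.904473, abundance = 1),
    Si = list(mass = c(27.9769265325, 28.976494700, 29.97377017),
              abundance = c(0.92223, 0.04685, 0.03092)),
    Se = list(mass = c(73.9224764, 75.9192136, 76.9199140, 77.9173091,
                       79.9165213, 81.9166994),
              abundance = c(0.0089, 0.0937, 0.0763, 0.2377, 0.4961, 0.0873)),
    B  = list(mass = c(10.0129370, 11.0093054), abundance = c(0.199, 0.801)),
    Li = list(mass = c(6.015122795, 7.01600455), abundance = c(0.0759, 0.9241)),
    Be = list(mass = 9.0121822, abundance = 1),
    He = list(mass = 4.002602, abundance = 1),
    Mg = list(mass = c(23.98504170, 24.98583692, 25.982592929),
              abundance = c(0.7899, 0.1000, 0.1101)),
    Al = list(mass = 26.98153863, abundance = 1),
    Ca = list(mass = c(39.96259098, 41.95861801, 42.9587666, 43.9554818,
                       47.952534),
              abundance = c(0.96941, 0.00647, 0.00135, 0.02086, 0.00187)),
    Fe = list(mass = c(53.9396105, 55.9349375, 56.9353940, 57.9332756),
              abundance = c(0.05845, 0.91754, 0.02119, 0.00282)),
    Cu = list(mass = c(62.9295975, 64.9277895), abundance = c(0.6917, 0.3083)),
    Zn = list(mass = c(63.9291422, 65.9260334, 66.9271273, 67.9248442,
                       69.9253193),
              abundance = c(0.4863, 0.2790, 0.0410, 0.1875, 0.0062)),
    Mn = list(mass = 54.9380451, abundance = 1),
    Co = list(mass = 58.9331950, abundance = 1),
    Ni = list(mass = c(57.9353429, 59.9307864, 60.9310560, 61.9283451,
                       63.9279660),
              abundance = c(0.680769, 0.262231, 0.011399, 0.036345, 0.009256)),
    As = list(mass = 74.9215965, abundance = 1),
    Sc = list(mass = 44.9559119, abundance = 1),
    Ti = list(mass = c(45.9526316, 46.9517631, 47.9479463, 48.9478700,
                       49.9447912),
              abundance = c(0.0825, 0.0744, 0.7372, 0.0541, 0.0518)),
    V  = list(mass = c(49.9471585, 50.9439595), abundance = c(0.0025, 0.9975)),
    Cr = list(mass = c(49.9460442, 51.9405075, 52.9406494, 53.9388804),
              abundance = c(0.04345, 0.83789, 0.09501, 0.02365)),
    Ga = list(mass = c(68.9255736, 70.9247013), abundance = c(0.60108, 0.39892)),
    Ge = list(mass = 73.9211778, abundance = 1),
    Rb = list(mass = c(84.911789738, 86.909180527), abundance = c(0.7217, 0.2783)),
    Sr = list(mass = 87.9056121, abundance = 1),
    Y  = list(mass = 88.9058483, abundance = 1),
    Zr = list(mass = 89.9047044, abundance = 1),
    Nb = list(mass = 92.9063781, abundance = 1),
    Mo = list(mass = 97.9054082, abundance = 1),
    Ru = list(mass = 101.9043493, abundance = 1),
    Rh = list(mass = 102.905504, abundance = 1),
    Pd = list(mass = 105.903486, abundance = 1),
    Ag = list(mass = c(106.905097, 108.904752), abundance = c(0.51839, 0.48161)),
    Cd = list(mass = 113.9033585, abundance = 1),
    In = list(mass = c(112.904058, 114.903878), abundance = c(0.0429, 0.9571)),
    Sn = list(mass = 119.9021947, abundance = 1),
    Sb = list(mass = c(120.9038157, 122.9042140), abundance = c(0.5721, 0.4279)),
    Te = list(mass = 129.9062244, abundance = 1),
    Cs = list(mass = 132.905451933, abundance = 1),
    Ba = list(mass = 137.9052472, abundance = 1),
    La = list(mass = 138.9063533, abundance = 1),
    Ce = list(mass = 139.9054387, abundance = 1),
    Pr = list(mass = 140.9076528, abundance = 1),
    Nd = list(mass = 141.9077233, abundance = 1),
    Sm = list(mass = 151.9197324, abundance = 1),
    Eu = list(mass = c(150.9198502, 152.9212303), abundance = c(0.4781, 0.5219)),
    Gd = list(mass = 157.9241039, abundance = 1),
    Tb = list(mass = 158.9253468, abundance = 1),
    Dy = list(mass = 163.9291748, abundance = 1),
    Ho = list(mass = 164.9303221, abundance = 1),
    Er = list(mass = 165.9302931, abundance = 1),
    Tm = list(mass = 168.9342133, abundance = 1),
    Yb = list(mass = 173.9388621, abundance = 1),
    Lu = list(mass = 174.9407718, abundance = 1),
    Hf = list(mass = 179.9465500, abundance = 1),
    Ta = list(mass = 180.9479958, abundance = 1),
    W  = list(mass = 183.9509312, abundance = 1),
    Re = list(mass = c(184.9529550, 186.9557531), abundance = c(0.374, 0.626)),
    Os = list(mass = 191.9614807, abundance = 1),
    Ir = list(mass = c(190.9605940, 192.9629264), abundance = c(0.373, 0.627)),
    Pt = list(mass = 194.9647911, abundance = 1),
    Au = list(mass = 196.9665687, abundance = 1),
    Hg = list(mass = 201.9706430, abundance = 1),
    Tl = list(mass = c(202.9723442, 204.9744275), abundance = c(0.29524, 0.70476)),
    Pb = list(mass = c(203.9730436, 205.9744653, 206.9758969, 207.9766521),
              abundance = c(0.014, 0.241, 0.221, 0.524)),
    Bi = list(mass = 208.9803987, abundance = 1),
    Th = list(mass = 232.0380553, abundance = 1),
    U  = list(mass = 238.0507882, abundance = 1)
  )
  # normalize abundances defensively so each element sums to exactly 1
  lapply(e, function(x) {
    o <- order(x$mass)
    list(mass = x$mass[o], abundance = x$abundance[o] / sum(x$abundance))
  })
})

#' Element isotope table
#'
#' @return Named list; each element holds `mass` (ascending isotopic masses
#'   in u) and `abundance` (natural abundances summing to 1).
#' @export
isotope_table <- function() .isotope_data

#' Elements known to the isotope table
#' @return Character vector of element symbols.
#' @export
isotope_elements <- function() names(.isotope_data)

#' Default universe of implausible decoy adducts
#'
#' Single-element attachments chemically implausible as ionization adducts,
#' used to generate decoy ions for FDR estimation. User-overridable wherever
#' a decoy universe is taken; the shipped list is a stand-in since no
#' canonical published list exists. Elements that are plausible target
#' adducts (`H`, `Na`, `K`) are excluded by construction.
#'
#' @return Character vector of `"+X"` adduct strings.
#' @export
default_decoy_adducts <- function() {
  els <- c("He", "Li", "Be", "B", "F", "Al", "Si", "P", "Cl", "Sc", "Ti",
           "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As",
           "Se", "Br", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd",
           "Ag", "Cd", "In", "Sn", "Sb", "Te", "I", "Cs", "Ba", "La", "Ce",
           "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
           "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl",
           "Pb", "Bi", "Th", "U")
  paste0("+", els)
}
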