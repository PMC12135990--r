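#' @import methods
#' @importFrom stats approx dist rnorm runif setNames sd
#' @importFrom utils read.csv write.csv head tail
NULL

## Built-in element constants for the atom types found in dry protein
## structures (plus common counter-ions).  Masses in Da (IUPAC 2021 standard
## atomic weights), electron counts Z, van der Waals radii in Angstrom
## (Bondi).  Unknown elements are a hard error, never a silent default.
.element_table <- data.frame(
  element   = c("H", "C", "N", "O", "S", "SE", "P",
                "NA", "MG", "K", "CA", "CL", "ZN", "FE", "MN", "CU"),
  electrons = c(1L, 6L, 7L, 8L, 16L, 34L, 15L,
                11L, 12L, 19L, 20L, 17L, 30L, 26L, 25L, 29L),
  mass      = c(1.008, 12.011, 14.007, 15.999, 32.06, 78.971, 30.974,
                22.990, 24.305, 39.098, 40.078, 35.45, 65.38, 55.845,
                54.938, 63.546),
  vdw       = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.90, 1.80,
                2.27, 1.73, 2.75, 2.31, 1.75, 1.39, 2.05, 2.05, 1.40),
  stringsAsFactors = FALSE
)

## 4-Gaussian Cromer-Mann X-ray form factor coefficients
## (International Tables for Crystallography, Vol. C):
## f(q) = sum_k a_k exp(-b_k (q / 4 pi)^2) + c
.cromer_mann <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  SE = list(a = c(17.0006, 5.81960, 3.97310, 4.35430),
            b = c(2.40980, 0.272600, 15.2372, 43.8163), c = 2.84090),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490)
)

.lookup_element <- function(element) {
  el <- toupper(element)
  idx <- match(el, .element_table$element)
  if (anyNA(idx)) {
    bad <- unique(el[is.na(idx)])
    stop("unknown element(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(.element_table$element, collapse = ", "))
  }
  .element_table[idx, , drop = FALSE]
}

## Infer element symbols from PDB atom names when the element column is
## absent or blank: strip leading digits, take the leading alphabetic
## character(s); two-letter symbols recognised case-insensitively.
.element_from_name <- function(name) {
  nm <- toupper(gsub("^[0-9 ]+", "", name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "CU"), two, one)
}

.cm_form_factor <- function(element, q) {
  el <- toupper(element)
  cm <- .cromer_mann[[el]]
  if (is.null(cm))
    stop("no Cromer-Mann coefficients for element ", element)
  s2 <- (q / (4 * pi))^2
  f <- rep(cm$c, length(q))
  for (k in 1:4) f <- f + cm$a[k] * exp(-cm$b[k] * s2)
  f
}
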