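# Shared internal helpers.  Units everywhere inside the package: nm, ns, amu,
# molar; conversion happens only at I/O boundaries (Angstrom-native formats)
# and at rate reporting (to_bimolecular).

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

rownorms <- function(m) sqrt(rowSums(m * m))

## Avogadro constant (mol^-1); nm^3 -> litre is 1e-24
.N_A <- 6.02214076e23

#' Number of ions implied by a molar concentration in a box
#'
#' @param concentration molar concentration (mol/L)
#' @param box numeric length-3 vector of orthorhombic box edges (nm)
#' @return integer ion count, rounded to the nearest whole ion
#' @examples
#' ions_for_concentration(0.15, c(8, 8, 8))
#' @export
ions_for_concentration <- function(concentration, box) {
  stopifnot(is_scalar_num(concentration), concentration > 0,
            is.numeric(box), length(box) == 3L, all(box > 0))
  as.integer(round(concentration * .N_A * prod(box) * 1e-24))
}

## Run code with a temporary RNG state; restores (or clears) the global seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed spawning: one global seed fans out into independent
## child seeds (one per replica or stage) so any replica can be regenerated in
## isolation.  Scheme: seed the generator with (seed + 779279 * stream) and
## draw n integers below 2^31 - 1.
spawn_seeds <- function(seed, n, stream = 0L) {
  stopifnot(is_count(seed), is_count(n))
  with_seed((seed + 779279 * stream) %% (.Machine$integer.max - 1L),
            sample.int(.Machine$integer.max - 1L, n))
}

## Element inference from atom names (PDB files with a blank element column,
## GRO files which have none).  Ions first, then the leading alphabetic
## character.
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, Na = 22.98977, Cl = 35.453,
                   K = 39.098, Mg = 24.305, Ca = 40.078, Fe = 55.845)

infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  out <- character(length(nm))
  out[nm %in% c("NA", "SOD")] <- "Na"
  out[nm %in% c("CL", "CLA")] <- "Cl"
  out[nm %in% c("K", "POT")] <- "K"
  out[nm %in% c("MG")] <- "Mg"
  rest <- out == ""
  first <- substr(nm[rest], 1L, 1L)
  known <- c("H", "C", "N", "O", "P", "S")
  out[rest] <- ifelse(first %in% known, first, "C")
  out
}

mass_of_element <- function(element) {
  m <- .ELEMENT_MASS[element]
  m[is.na(m)] <- 12.011
  unname(m)
}
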