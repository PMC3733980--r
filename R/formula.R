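## Elemental formulas are named integer vectors over c(C, H, N, O, S).

ELEMENTS <- c("C", "H", "N", "O", "S")

#' Construct an elemental formula
#'
#' @param C,H,N,O,S Non-negative integer atom counts.
#' @return A named numeric vector of atom counts with class
#'   `"elemental_formula"`.
#' @examples
#' elemental_formula(C = 2, H = 5, N = 1, O = 2)  # glycine
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  counts <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_invalid("atom counts must be non-negative integers")
  structure(as.numeric(counts), names = ELEMENTS,
            class = "elemental_formula")
}

as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    out <- setNames(numeric(length(ELEMENTS)), ELEMENTS)
    bad <- setdiff(names(x), ELEMENTS)
    if (length(bad)) stop_invalid("unknown element(s): %s",
                                  paste(bad, collapse = ", "))
    out[names(x)] <- x
    return(do.call(elemental_formula, as.list(out)))
  }
  stop_invalid("cannot interpret object as an elemental formula")
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  as_formula(unclass(as_formula(e1)) + unclass(as_formula(e2)))
}

#' @export
print.elemental_formula <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) {
    cat("<empty formula>\n")
  } else {
    cat(paste0(names(nz), ifelse(nz > 1, nz, "")), "\n", sep = "")
  }
  invisible(x)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum over elements of atom count times the exact mass of the lightest
#' stable isotope.
#'
#' @param formula An [elemental_formula()] (or named count vector).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(elemental_formula(H = 2, O = 1))  # water, 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  formula <- as_formula(formula)
  tab <- .isotopes[.isotopes$offset == 0L, ]
  light <- setNames(tab$mass, tab$element)
  sum(unclass(formula) * light[ELEMENTS])
}

#' Protonated (singly or multiply charged) m/z
#'
#' MALDI produces predominantly singly protonated ions; the default charge
#' is therefore 1 and the m/z of \[M+H\]+ is M + 1.00728.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z in Da.
#' @export
protonated_mz <- function(mass, charge = 1L) {
  if (charge < 1 || charge != round(charge))
    stop_invalid("charge must be a positive integer")
  (mass + charge * PROTON_MASS) / charge
}
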