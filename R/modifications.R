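#' Modification specifications
#'
#' Constructors for the mass modifications considered by the search:
#' carbamidomethylation of cysteine (fixed), oxidation of methionine,
#' citrullination (deimination) of arginine, and deamidation of
#' asparagine/glutamine. Citrullination and deamidation share the same
#' +0.984016 Da monoisotopic delta, which is why site assignment must
#' weigh both. A citrullinated arginine loses the basic guanidinium
#' group trypsin recognizes, so citrullination blocks cleavage.
#'
#' @param name Modification name.
#' @param delta Monoisotopic mass shift in Da (finite).
#' @param targets Character vector of residue letters the modification
#'   can sit on (non-empty).
#' @param blocks_cleavage Does the modification abolish tryptic cleavage
#'   at its residue?
#' @return A `mod_spec` object (list with the four fields).
#' @examples
#' mod_citrullination()$delta  # 0.984016
#' @export
mod_spec <- function(name, delta, targets, blocks_cleavage = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.character(targets), length(targets) >= 1L,
            all(nchar(targets) == 1L),
            is.logical(blocks_cleavage), length(blocks_cleavage) == 1L)
  structure(
    list(name = name, delta = delta, targets = toupper(targets),
         blocks_cleavage = blocks_cleavage),
    class = "mod_spec"
  )
}

#' @rdname mod_spec
#' @export
mod_citrullination <- function() {
  mod_spec("citrullination", cit_delta(), "R", blocks_cleavage = TRUE)
}

#' @rdname mod_spec
#' @export
mod_deamidation <- function() {
  mod_spec("deamidation", cit_delta(), c("N", "Q"))
}

#' @rdname mod_spec
#' @export
mod_oxidation <- function() {
  mod_spec("oxidation", formula_mass(c(O = 1)), "M")
}

#' @rdname mod_spec
#' @export
mod_carbamidomethyl <- function() {
  mod_spec("carbamidomethyl", formula_mass(c(C = 2, H = 3, N = 1, O = 1)), "C")
}

#' @export
print.mod_spec <- function(x, ...) {
  cat(sprintf("<mod_spec> %s %+0.6f Da on [%s]%s\n", x$name, x$delta,
              paste(x$targets, collapse = ""),
              if (x$blocks_cleavage) " (blocks cleavage)" else ""))
  invisible(x)
}

#' Construct a modified peptide
#'
#' A peptide sequence with zero or more positioned mass modifications;
#' the unit of identification for spectrum matching and site
#' localization.
#'
#' @param sequence Uppercase amino-acid string over the 20 standard
#'   letters.
#' @param mods A list of `mod_spec`s named/positioned by `positions`, or
#'   NULL for the unmodified peptide.
#' @param positions Integer vector, 1-based within the peptide, parallel
#'   to `mods`. Each position must carry a residue in the mod's target
#'   set; at most one modification per position.
#' @param charge Optional precursor charge hint (positive integer).
#' @return A `modified_peptide` object.
#' @examples
#' mp <- modified_peptide("ETYMLSSLARVKTR",
#'                        mods = list(mod_citrullination(), mod_citrullination()),
#'                        positions = c(10, 14))
#' peptide_mass(mp)
#' @export
modified_peptide <- function(sequence, mods = NULL, positions = integer(),
                             charge = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "")[[1]]
  bad <- which(!residues %in% names(residue_formulas))
  if (length(bad)) {
    stop("unknown residue letter '", residues[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  if (is.null(mods)) mods <- list()
  if (inherits(mods, "mod_spec")) mods <- list(mods)
  positions <- as.integer(positions)
  stopifnot(length(mods) == length(positions))
  if (anyDuplicated(positions)) {
    stop("at most one modification per position", call. = FALSE)
  }
  for (i in seq_along(mods)) {
    stopifnot(inherits(mods[[i]], "mod_spec"))
    p <- positions[i]
    if (p < 1L || p > length(residues)) {
      stop("modification position ", p, " outside peptide", call. = FALSE)
    }
    if (!residues[p] %in% mods[[i]]$targets) {
      stop("residue '", residues[p], "' at position ", p,
           " is not a target of ", mods[[i]]$name, call. = FALSE)
    }
  }
  ord <- order(positions)
  structure(
    list(sequence = sequence, mods = mods[ord],
         positions = positions[ord], charge = charge),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  ann <- if (length(x$positions)) {
    paste(sprintf("%s@%d", vapply(x$mods, `[[`, "", "name"), x$positions),
          collapse = ", ")
  } else "unmodified"
  cat(sprintf("<modified_peptide> %s (%s)\n", x$sequence, ann))
  invisible(x)
}

#' Positions of citrullination sites within a modified peptide
#' @param mp A `modified_peptide`.
#' @return Integer vector of 1-based peptide positions.
#' @export
cit_positions <- function(mp) {
  stopifnot(inherits(mp, "modified_peptide"))
  mod_names <- vapply(mp$mods, `[[`, "", "name")
  mp$positions[mod_names == "citrullination"]
}
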