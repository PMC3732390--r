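#' Species and transcription factors of the reference study design
#'
#' Five mouse taxa (laboratory strains C57BL/6J and A/J, wild-derived
#' CAST/EiJ, and the species SPRET/EiJ and Caroli/EiJ) with rat as
#' outgroup; three liver master regulators plus CTCF as control.
#' Identifiers are file-system safe.
#' @export
STUDY_SPECIES <- c("C57BL6J", "AJ", "CAST", "SPRET", "CAROLI", "RAT")

#' @rdname STUDY_SPECIES
#' @export
MOUSE_SPECIES <- c("C57BL6J", "AJ", "CAST", "SPRET", "CAROLI")

#' @rdname STUDY_SPECIES
#' @export
STUDY_TFS <- c("CEBPA", "HNF4A", "FOXA1")

#' Default divergence times from the C57BL/6J anchor, in million years
#' (MY): A/J 0.5, CAST/EiJ 1, SPRET/EiJ 3, Caroli/EiJ 6, rat 20.
#' @rdname STUDY_SPECIES
#' @export
STUDY_DIVERGENCE_MY <- c(AJ = 0.5, CAST = 1, SPRET = 3, CAROLI = 6,
                         RAT = 20)

#' Build the fixed study phylogeny
#'
#' Rooted ultrametric topology
#' `(((((C57BL6J, AJ), CAST), SPRET), CAROLI), RAT)` with branch lengths in
#' million years.  The four internal nodes of the mouse clade are labelled
#' `A1` (most recent common ancestor of C57BL/6J and A/J) through `A4`
#' (root of the mouse clade); these are the four ancestors whose binding
#' intensities are reconstructed by parsimony.
#'
#' @param times named numeric vector of split ages (MY from the C57BL/6J
#'   anchor) for `AJ`, `CAST`, `SPRET`, `CAROLI`, `RAT`; defaults to
#'   [STUDY_DIVERGENCE_MY].
#' @return an [ape::phylo] tree with node labels `A1`..`A4` and `ROOT`.
#' @export
build_study_phylogeny <- function(times = STUDY_DIVERGENCE_MY) {
  t <- STUDY_DIVERGENCE_MY
  t[names(times)] <- times
  if (any(t <= 0)) stop("split ages must be positive")
  if (is.unsorted(t[c("AJ", "CAST", "SPRET", "CAROLI", "RAT")]))
    stop("split ages must increase from AJ to RAT")
  txt <- sprintf(
    paste0("(((((C57BL6J:%g,AJ:%g)A1:%g,CAST:%g)A2:%g,SPRET:%g)A3:%g,",
           "CAROLI:%g)A4:%g,RAT:%g)ROOT;"),
    t["AJ"], t["AJ"], t["CAST"] - t["AJ"], t["CAST"],
    t["SPRET"] - t["CAST"], t["SPRET"], t["CAROLI"] - t["SPRET"],
    t["CAROLI"], t["RAT"] - t["CAROLI"], t["RAT"])
  ape::read.tree(text = txt)
}

#' Extract the five-leaf mouse clade of the study phylogeny
#' @param tree a tree from [build_study_phylogeny].
#' @return an [ape::phylo] with the rat outgroup removed.
#' @export
mouse_clade <- function(tree) ape::drop.tip(tree, "RAT")
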