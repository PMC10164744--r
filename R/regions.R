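#' Anatomical region sets (AAL atlas labels)
#'
#' The two regions analysed throughout: the parieto-occipital cortex (10
#' parietal, 12 occipital and 2 posterior cingulate AAL ROIs, 24 in total —
#' the cortical generators of the dominant posterior alpha rhythm) and the
#' left and right hippocampi.
#'
#' @return Named list of character vectors of AAL ROI labels.
#' @export
aal_region_sets <- function() {
  list(
    parieto_occipital = c(
      "Parietal_Sup_L", "Parietal_Sup_R", "Parietal_Inf_L", "Parietal_Inf_R",
      "SupraMarginal_L", "SupraMarginal_R", "Angular_L", "Angular_R",
      "Precuneus_L", "Precuneus_R",
      "Calcarine_L", "Calcarine_R", "Cuneus_L", "Cuneus_R",
      "Lingual_L", "Lingual_R", "Occipital_Sup_L", "Occipital_Sup_R",
      "Occipital_Mid_L", "Occipital_Mid_R", "Occipital_Inf_L", "Occipital_Inf_R",
      "Cingulum_Post_L", "Cingulum_Post_R"
    ),
    hippocampi = c("Hippocampus_L", "Hippocampus_R")
  )
}

#' Region-set constructor
#'
#' Resolves either a named anatomical set (`"parieto_occipital"`,
#' `"hippocampi"`) or an explicit label vector (for synthetic cohorts).
#'
#' @param name Region name.
#' @param members Optional explicit ROI label vector; required for names other
#'   than the built-in anatomical sets.
#' @return A `region_set` list with `name` and `members`.
#' @export
region_set <- function(name, members = NULL) {
  builtin <- aal_region_sets()
  if (is.null(members)) {
    if (!name %in% names(builtin)) {
      rlang::abort(sprintf("unknown region set '%s'; supply `members`.", name))
    }
    members <- builtin[[name]]
  }
  if (name == "parieto_occipital" && length(members) != 24) {
    rlang::abort("parieto_occipital must have exactly 24 members.")
  }
  if (name == "hippocampi" && length(members) != 2) {
    rlang::abort("hippocampi must have exactly 2 members.")
  }
  if (anyDuplicated(members)) rlang::abort("region members must be unique.")
  structure(list(name = name, members = members), class = "region_set")
}
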