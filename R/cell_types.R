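#' Default immunophenotypic cell-type table
#'
#' The default label set used throughout the package: 32 immunophenotypic
#' blood cell types grouped into 7 lineage families (HSPC, B, NK, T,
#' monocyte, neutrophil, erythrocyte).  Quality-control mapping-rate
#' thresholds are applied per family (see [family_mapping_thresholds()]),
#' so any user-supplied replacement table only needs the two columns
#' `cell_type` and `family`.
#'
#' @return A `data.frame` with columns `cell_type` (32 unique labels) and
#'   `family` (one of `"HSPC"`, `"B"`, `"NK"`, `"T"`, `"monocyte"`,
#'   `"neutrophil"`, `"erythrocyte"`).
#' @export
#' @examples
#' table(abc_cell_types()$family)
abc_cell_types <- function() {
  fam <- list(
    HSPC        = c("HSC", "MPP", "MLP", "LMPP", "CMP", "GMP", "MEP", "CLP"),
    B           = c("pro_B", "pre_B", "naive_B", "memory_B", "regulatory_B",
                    "plasma_cell"),
    NK          = c("NK_progenitor", "immature_NK", "cytotoxic_NK",
                    "cytokine_NK"),
    T           = c("CD4_naive_T", "CD4_memory_T", "CD4_effector_T",
                    "CD8_naive_T", "CD8_memory_T", "CD8_effector_T"),
    monocyte    = c("monocyte_progenitor", "classical_monocyte",
                    "nonclassical_monocyte"),
    neutrophil  = c("neutrophil_progenitor", "immature_neutrophil",
                    "mature_neutrophil"),
    erythrocyte = c("erythroid_progenitor", "nucleated_erythrocyte")
  )
  data.frame(
    cell_type = unlist(fam, use.names = FALSE),
    family    = rep(names(fam), lengths(fam)),
    stringsAsFactors = FALSE
  )
}

#' Mapping-rate retention thresholds per lineage family
#'
#' Cells whose per-cell mapping rate falls strictly below the threshold of
#' their lineage family are discarded during quality control: 10% for
#' HSPCs and monocytes, 5% for B cells, NK cells, neutrophils and
#' erythrocytes, and 2.5% for T cells.
#'
#' @return Named numeric vector of thresholds on the \[0, 1\] scale.
#' @export
family_mapping_thresholds <- function() {
  c(HSPC = 0.10, monocyte = 0.10,
    B = 0.05, NK = 0.05, neutrophil = 0.05, erythrocyte = 0.05,
    T = 0.025)
}

#' Resolve the lineage family of cell-type labels
#'
#' @param cell_type Character vector of cell-type labels.
#' @param type_table Lookup table with columns `cell_type` and `family`
#'   (default [abc_cell_types()]).
#' @return Character vector of family names, same length as `cell_type`.
#'   Unknown labels are a fatal error (they would otherwise silently
#'   escape the QC thresholds).
#' @export
cell_family <- function(cell_type, type_table = abc_cell_types()) {
  idx <- match(cell_type, type_table$cell_type)
  if (anyNA(idx)) {
    bad <- unique(cell_type[is.na(idx)])
    stop("cell type(s) with no lineage family: ", paste(bad, collapse = ", "))
  }
  type_table$family[idx]
}
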