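#' Default 27-phenotype breast tumor palette
#'
#' The default palette mirrors the 27-class phenotype taxonomy of
#' multiplexed breast tumor imaging: 6 immune, 7 stromal and 14
#' epithelial phenotypes. Pairwise interactions over this palette give
#' the 378 interaction features split into 273 tumor-microenvironment
#' (TMI) pairs and 105 tumor-core (TCI, epithelial-epithelial) pairs.
#'
#' @return A \code{\link{PhenotypePalette}} with 27 phenotypes.
#' @examples
#' pal <- defaultPalette()
#' table(phenotypeClass(pal))
#' @export
defaultPalette <- function() {
  immune <- c("Macrophage_1", "Macrophage_2", "T_and_B_Cells", "T_Cells",
              "B_Cells", "Vim_hi_Immune")
  stromal <- c("Endothelial", "Vim_hi_Fibroblast", "Small_Circular_Fibroblast",
               "Small_Elongated_Fibroblast", "Large_Elongated_Fibroblast",
               "Fibronectin_hi_Fibroblast", "Myofibroblast")
  epithelial <- c("Myoepithelial", "Hypoxic_Epithelial", "Apoptotic_Epithelial",
                  "Proliferative_Epithelial", "CK7_CK_hi_Cadherin_hi_Epithelial",
                  "CK_low_HR_low_Epithelial", "CK_low_HR_hi_p53_Epithelial",
                  "CK_hi_HR_hi_Epithelial", "CK_hi_HR_low_Epithelial",
                  "CK_low_HR_med_Epithelial", "Basal_CK_Epithelial",
                  "HER2_hi_Epithelial", "Luminal_CK_Epithelial",
                  "Epithelial_low_Expression")
  PhenotypePalette(c(immune, stromal, epithelial),
                   c(rep("immune", length(immune)),
                     rep("stromal", length(stromal)),
                     rep("epithelial", length(epithelial))))
}
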