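#' Classify per-gene expression trajectories across the three-group timeline
#'
#' From the three pairwise differential-expression tables (control vs
#' treatment, control vs withdrawal, treatment vs withdrawal) each gene is
#' assigned one dynamics class by an ordered decision table:
#'
#' 1. `persistent` - changed during treatment and did not restore:
#'    C_A20 and C_AD significant, same direction, A20_AD not significant.
#' 2. `partial_normalization` - partially normalized during withdrawal but
#'    still different from control: C_A20, C_AD and A20_AD all significant,
#'    same direction of the two control contrasts, and |log2FC(C_AD)| <
#'    |log2FC(C_A20)|.
#' 3. `deprivation_emergent` - changed only during withdrawal: C_A20 not
#'    significant, A20_AD and C_AD significant.
#' 4. `gradual_emergent` - drifted gradually, significant only cumulatively:
#'    C_A20 and A20_AD not significant, C_AD significant.
#' 5. `restored` - changed during treatment, back to control afterwards:
#'    C_A20 significant, C_AD not significant.
#' 6. `unclassified` - any other flag combination.
#'
#' A log2 fold change of exactly zero is treated as agreeing with either
#' direction. The table is exhaustive and mutually exclusive: every flag
#' combination maps to exactly one class.
#'
#' @param deg_c_trt `deg_table` for control vs treatment (C_A20).
#' @param deg_c_wd `deg_table` for control vs withdrawal (C_AD).
#' @param deg_trt_wd `deg_table` for treatment vs withdrawal (A20_AD).
#' @return Data frame of class `trajectory_calls`: `gene`, `class` (factor
#'   over the five classes plus `unclassified`), the three significance
#'   flags, the two control-contrast directions, and the three log2FCs.
#' @export
classify_trajectory <- function(deg_c_trt, deg_c_wd, deg_trt_wd) {
  for (d in list(deg_c_trt, deg_c_wd, deg_trt_wd))
    stopifnot(inherits(d, "deg_table"))
  genes <- deg_c_trt$gene
  if (!setequal(genes, deg_c_wd$gene) || !setequal(genes, deg_trt_wd$gene))
    stop("the three contrasts must cover the same gene universe")
  iwd <- match(genes, deg_c_wd$gene)
  imd <- match(genes, deg_trt_wd$gene)
  sigA <- deg_c_trt$significant
  sigD <- deg_c_wd$significant[iwd]
  sigM <- deg_trt_wd$significant[imd]
  fcA <- deg_c_trt$log2fc
  fcD <- deg_c_wd$log2fc[iwd]
  fcM <- deg_trt_wd$log2fc[imd]
  same_dir <- sign(fcA) == sign(fcD) | fcA == 0 | fcD == 0
  cls <- rep("unclassified", length(genes))
  cls[sigA & sigD & same_dir & !sigM] <- "persistent"
  cls[sigA & sigD & same_dir & sigM & abs(fcD) < abs(fcA) &
        cls == "unclassified"] <- "partial_normalization"
  cls[!sigA & sigM & sigD & cls == "unclassified"] <- "deprivation_emergent"
  cls[!sigA & !sigM & sigD & cls == "unclassified"] <- "gradual_emergent"
  cls[sigA & !sigD & cls == "unclassified"] <- "restored"
  out <- data.frame(gene = genes,
                    class = factor(cls, levels = c(trajectory_classes(),
                                                   "unclassified")),
                    sig_c_trt = sigA, sig_c_wd = sigD, sig_trt_wd = sigM,
                    dir_c_trt = sign(fcA), dir_c_wd = sign(fcD),
                    log2fc_c_trt = fcA, log2fc_c_wd = fcD,
                    log2fc_trt_wd = fcM,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("trajectory_calls", "data.frame")
  out
}
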