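#' Default cell-cycle signature gene lists
#'
#' Short literature-standard S-phase and G2/M marker lists (human gene
#' symbols) for [score_cell_cycle()]. These are configurable defaults, not a
#' fixed reference: supply your own lists for other species or naming
#' schemes.
#'
#' @return list with character vectors `s` and `g2m`.
#' @export
cycle_signatures <- function() {
  list(
    s = c("MCM2", "MCM3", "MCM4", "MCM5", "MCM6", "MCM7", "PCNA", "RRM1",
          "RRM2", "TYMS", "FEN1", "RFC4", "GINS2", "CDC6", "CDC45", "UNG",
          "POLA1", "CHAF1B", "HELLS", "DSCC1"),
    g2m = c("MKI67", "TOP2A", "CCNB1", "CCNB2", "CDK1", "AURKA", "AURKB",
            "BUB1", "PLK1", "CENPA", "CENPE", "CENPF", "UBE2C", "BIRC5",
            "TPX2", "KIF11", "KIF23", "NUSAP1", "CDC20", "CKS2"))
}
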