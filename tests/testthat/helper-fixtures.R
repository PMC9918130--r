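## Small deterministic expression matrix: g genes x (3 groups x k samples),
## log-normal around log2 FPKM = 4, optional planted shift on gene 1 in the
## second group.
toy_expression <- function(g = 20, k = 4, shift = 0, noise = 0.1, seed = 42) {
  set.seed(seed)
  groups <- c("C", "A20", "AD")
  samples <- paste0(rep(groups, each = k), "_", rep(seq_len(k), 3))
  lx <- matrix(rnorm(g * 3 * k, 4, noise), g, 3 * k,
               dimnames = list(sprintf("g%02d", seq_len(g)), samples))
  lx[1, (k + 1):(2 * k)] <- lx[1, (k + 1):(2 * k)] + shift
  expression_matrix(2^lx, setNames(rep(groups, each = k), samples))
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "plsdaRank", mustWork = TRUE)
}

fixture_annotation <- function() {
  read_annotation(fixture_path("annotation_synthetic.tsv"))
}
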