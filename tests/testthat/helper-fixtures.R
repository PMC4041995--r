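# Shared fixture builders: everything is generated in code at test time.

# Tiny layout: n_sets probe sets of ppps pairs each, plus optional controls.
tiny_layout <- function(n_sets = 3, ppps = 4, n_controls = 0) {
  ids <- c(sprintf("PS%02d_at", seq_len(n_sets)),
           if (n_controls > 0) sprintf("AFFX-C%02d", seq_len(n_controls)))
  chip_layout(rep(ids, each = ppps))
}

# Intensity table with deterministic values.
tiny_table <- function(layout, sample_id = "S1", base = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- layout$n_probe_pairs
  probe_intensity_table(sample_id,
                        pm = base + seq_len(n),
                        mm = (base + seq_len(n)) / 3,
                        layout)
}

# Annotation rows for a single model across passages.
tiny_annotations <- function(model = "M1",
                             passages = c(P0 = 3, P1 = 5, P4 = 5, P10 = 5)) {
  do.call(rbind, lapply(names(passages), function(p) {
    data.frame(
      sample_id = sprintf("%s_%s_r%d", model, p, seq_len(passages[[p]])),
      model_name = model, passage = p,
      replicate_index = seq_len(passages[[p]]),
      rna_species = "human", tumor_class = "synthetic",
      stringsAsFactors = FALSE
    )
  }))
}

# Expression matrix with named samples drawn from annotations.
expr_from_annotations <- function(annotations, n_sets = 50, seed = 1,
                                  base_mean = 8, sd = 0.2) {
  set.seed(seed)
  ids <- sprintf("PS%03d_at", seq_len(n_sets))
  m <- matrix(rnorm(n_sets * nrow(annotations), base_mean, sd),
              n_sets, nrow(annotations),
              dimnames = list(ids, annotations$sample_id))
  m
}

# Independent brute-force one-sided signed-rank p-value: enumerate all
# 2^n sign assignments of the ranked |d| and count statistics >= observed.
brute_force_signed_rank_p <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all >= w_obs - 1e-9)
}

# Independent hypergeometric upper tail by direct pmf summation with
# choose() ratios (no phyper).
sum_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk) / choose(N, n))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "xenomine", mustWork = TRUE)
}
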