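# Independent oracles and shared fixtures for the test suite. Each oracle
# re-derives the quantity from first principles so it never shares code with
# the implementation it checks.

# Kruskal-Wallis H from ranks, with tie correction, and its chi-square
# p-value. H = [12 / (N(N+1))] * sum n_i (Rbar_i - (N+1)/2)^2, divided by
# 1 - sum(t^3 - t) / (N^3 - N) over tie groups.
kw_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  list(statistic = h,
       p_value = stats::pchisq(h, nlevels(groups) - 1, lower.tail = FALSE))
}

# Product-limit survival estimate at each requested time, built directly
# from risk sets: S(t) = prod over event times u <= t of (1 - d_u / n_u).
km_oracle <- function(time, event, at) {
  ev_times <- sort(unique(time[event == 1]))
  vapply(at, function(t) {
    s <- 1
    for (u in ev_times[ev_times <= t]) {
      n_u <- sum(time >= u)
      d_u <- sum(time == u & event == 1)
      s <- s * (1 - d_u / n_u)
    }
    s
  }, numeric(1))
}

# Brute-force probe collapse: group probes by gene, drop non-unique
# mappings, keep the argmax-CV probe per gene.
collapse_oracle <- function(x, annot) {
  tab <- table(annot$probe_id)
  uniq <- names(tab)[tab == 1]
  ann <- annot[annot$probe_id %in% uniq & !is.na(annot$gene_symbol) &
                 annot$gene_symbol != "", ]
  keep <- character(0)
  for (g in unique(ann$gene_symbol)) {
    probes <- intersect(rownames(x), ann$probe_id[ann$gene_symbol == g])
    if (!length(probes)) next
    cv <- vapply(probes, function(p) {
      stats::sd(x[p, ]) / mean(x[p, ])
    }, numeric(1))
    keep[g] <- probes[which.max(cv)]
  }
  keep
}

# Standard separable discovery fixture: planted signal genes at a 3-sd
# group shift among noise, 25 cell lines in 9/8/8 tertiles.
separable_fixture <- function(seed = 7, n_genes = 50, effect = 3) {
  gen_cell_line_dataset(n_cell_lines = 25, n_genes = n_genes,
                        n_signal_genes = 10, effect_size = effect,
                        noise_sd = 1, seed = seed)
}

# Tiny 4/4/4-group fixture whose 12 genes include a few informative ones;
# small enough that all 10-gene panels can be enumerated.
tiny_fixture <- function(seed = 21, n_signal = 3, effect = 2.5) {
  sim <- gen_cell_line_dataset(n_cell_lines = 12, n_genes = 12,
                               n_signal_genes = n_signal,
                               effect_size = effect, seed = seed)
  list(z = zscore_genes(sim$expression), groups = sim$groups,
       signal = sim$signal_genes)
}
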