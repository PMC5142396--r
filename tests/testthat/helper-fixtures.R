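# shared fixtures built in code

# reference panel shaped like a two-host validation panel: one clearly
# superior SP (NprE), one intermediate (YpjP), two overlapping weak SPs
# (AmyE, YwmC) and an empty-vector control
fig2_like_panel <- function() {
  reference_panel(
    sp_id = c("NprE", "YpjP", "AmyE", "YwmC", "empty"),
    mean_activity = c(5.0, 2.0, 0.9, 1.0, 0.05),
    sd_activity = c(0.30, 0.20, 0.15, 0.15, 0.05))
}

# fixture rows as normalize_by_max()-style records, one host
table1_records <- function(host = "C_glutamicum") {
  tab <- load_table1()
  tab <- tab[tab$host == host, ]
  data.frame(sp_id = tab$sp_id, host = tab$host,
             mean_activity = tab$mean_activity_U_per_mL,
             sd_activity = tab$sd_activity_U_per_mL,
             printed_relative = tab$relative_activity_pct,
             stringsAsFactors = FALSE)
}

# fixture rows with the *printed* relative column exposed for pairing
table1_printed_relatives <- function(host) {
  tab <- load_table1()
  tab <- tab[tab$host == host, ]
  data.frame(sp_id = tab$sp_id,
             relative_activity_pct = tab$relative_activity_pct,
             stringsAsFactors = FALSE)
}

# exhaustive enumeration over all N^n equiprobable pick sequences:
# per-member multiplicity pmf and the mean multiplicity spectrum
enumerate_picks <- function(n, N) {
  stopifnot(N^n <= 70000)
  grid <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  hits_member1 <- rowSums(grid == 1)
  pmf <- vapply(0:n, function(m) mean(hits_member1 == m), numeric(1))
  spectrum <- rowMeans(apply(grid, 1, function(seq) {
    per <- tabulate(seq, nbins = N)
    vapply(0:n, function(m) sum(per == m), numeric(1))
  }))
  list(pmf = pmf, spectrum = spectrum, m = 0:n)
}

# independently coded product-moment and mid-rank correlation oracle
oracle_correlations <- function(x, y) {
  pearson <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  midrank <- function(u) {
    o <- order(u)
    r <- numeric(length(u))
    r[o] <- seq_along(u)
    for (val in unique(u)) r[u == val] <- mean(r[u == val])
    r
  }
  list(pearson = pearson(x, y), spearman = pearson(midrank(x), midrank(y)))
}
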