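# Independent brute-force oracles and in-code fixtures.
# The oracles recount everything per threshold with explicit sums/loops and
# never share code paths with the package internals they check.

oracle_tail_counts <- function(ranked, grid) {
  do.call(rbind, lapply(grid, function(r) {
    above <- ranked$rank >= r
    N <- sum(above & !ranked$is_decoy & !ranked$is_modified)
    N_k <- sum(above & !ranked$is_decoy & ranked$is_modified)
    D <- sum(above & ranked$is_decoy)
    D_k <- sum(above & ranked$is_decoy & ranked$is_modified)
    Tt <- N + N_k
    data.frame(threshold = r, N = N, N_k = N_k, D = D, D_k = D_k, T = Tt,
               fdr = if (Tt > 0) D / Tt else if (D > 0) NA_real_ else 0)
  }))
}

# direct piecewise-affine evaluation with its own segment lookup
oracle_piecewise <- function(nodes, a, b, r) {
  vapply(r, function(x) {
    i <- 1L
    for (j in seq_len(length(nodes) - 1L)) {
      if (x >= nodes[j]) i <- j
    }
    min(max(a[i] + b[i] * x, 0), 1)
  }, 0)
}

oracle_transferred <- function(ranked, grid, nodes, a, b) {
  cnt <- oracle_tail_counts(ranked, grid)
  keep <- cnt$N_k > 0 & !is.na(cnt$fdr)
  cnt <- cnt[keep, ]
  g <- oracle_piecewise(nodes, a, b, cnt$threshold)
  data.frame(threshold = cnt$threshold,
             fdr_k = (cnt$N / cnt$N_k) * g * cnt$fdr)
}

oracle_separate <- function(ranked) {
  sub <- ranked[ranked$is_modified, ]
  g <- sort(unique(c(min(sub$rank), sub$rank[sub$is_decoy], max(sub$rank))))
  do.call(rbind, lapply(g, function(r) {
    D_k <- sum(sub$is_decoy & sub$rank >= r)
    T_k <- sum(!sub$is_decoy & sub$rank >= r)
    if (T_k == 0) return(NULL)
    data.frame(threshold = r, fdr_sep = D_k / T_k)
  }))
}

oracle_ols <- function(x, y) {
  # closed-form normal equations
  sx <- sum(x); sy <- sum(y); n <- length(x)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  a <- (sy - b * sx) / n
  c(a = a, b = b)
}

# a fixed two-segment continuous gamma model (continuity at rank 300:
# 0.2 + 5e-4*300 = 0.35)
fake_gamma_model <- function() {
  structure(list(nodes = c(1, 300, 1000), a = c(0.2, 0.35),
                 b = c(5e-4, 0), anchor = 300, anchored = TRUE,
                 r2 = NA_real_, rmse = NA_real_, n_points = 0L,
                 method = "spline-linear", dropped_knots = numeric()),
            class = "spline_linear_model")
}

# adversarial random PSM set: ties, arbitrary label mix
random_psm_set <- function(n, seed) {
  set.seed(seed)
  score <- round(rgamma(n, shape = 8, rate = 0.4), 1)  # ties on purpose
  data.table::data.table(
    file = "f1.mgf", scan = seq_len(n),
    charge = sample(2:3, n, replace = TRUE),
    peptide = replicate(n, paste(sample(c("A", "G", "S", "T", "K"), 8,
                                        replace = TRUE), collapse = "")),
    modifications = "",
    score = score,
    is_decoy = runif(n) < 0.3,
    is_modified = runif(n) < 0.35,
    proteins = "P1")
}

write_sim_table <- function(sim, path) {
  write_psm_table(sim, path)
  path
}

toy_proteome <- function() {
  set.seed(42)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  data.frame(
    accession = sprintf("P%05d", 1:10),
    description = sprintf("toy protein %d", 1:10),
    sequence = replicate(10, paste(sample(aa, 120, replace = TRUE),
                                   collapse = "")),
    origin = "real", stringsAsFactors = FALSE)
}

uniprot_fixture <- function(path, entries) {
  # entries: list of list(acc=, feats=list(c(pos, note)))
  lines <- unlist(lapply(entries, function(e) {
    c(sprintf("ID   %s_HUMAN              Reviewed;         120 AA.",
              e$acc),
      sprintf("AC   %s;", e$acc),
      unlist(lapply(e$feats, function(f) {
        c(sprintf("FT   MOD_RES         %s", f[1]),
          sprintf("FT                   /note=\"%s\"", f[2]))
      })),
      "//")
  }))
  writeLines(lines, path)
  path
}
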