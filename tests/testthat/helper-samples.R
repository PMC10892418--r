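# Small deterministic fixtures built in code.

# A tiny wide sample table with hand-set concentrations.
toy_samples <- function(district = "TestA") {
  tibble::tibble(
    sample_id = paste0("S", 1:4),
    district = district,
    x = c(0, 100, 200, 300),
    y = c(0, 50, 100, 150),
    As = c(7.80, 12.0, 20.0, 26.74),
    Hg = c(0.02, 0.05, 0.10, 0.34),
    Cd = c(0.11, 0.20, 0.40, 0.69),
    Cr = c(44.32, 55.0, 80.0, 100.09),
    Pb = c(9.85, 20.0, 30.0, 42.19),
    Cu = c(18.36, 25.0, 40.0, 50.84),
    Zn = c(55.0, 80.0, 120.0, 144.13)
  )
}

# Random positive sample table, seeded.
random_samples <- function(n, district = "Rand", seed = 42) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      sample_id = sprintf("%s-%04d", district, seq_len(n)),
      district = district,
      x = stats::runif(n, 0, 5000),
      y = stats::runif(n, 0, 5000)
    )
    for (m in metals()) out[[m]] <- stats::runif(n, 0.01, 150)
    out
  })
}

# Straight-line re-evaluation of the three index formulas, written
# independently of the package internals (scalar loops, no shared helpers).
oracle_indices <- function(samples, refs = reference_set(),
                           dialect = c("rms", "arithmetic")) {
  dialect <- match.arg(dialect)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    p <- numeric(0)
    e <- numeric(0)
    for (m in metals()) {
      c_i <- samples[[m]][i]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], metal = m, index_name = "Igeo",
        value = log(c_i / (refs$igeo_margin * refs$background[[m]])) / log(2))
      p[m] <- c_i / refs$standard[[m]]
      e[m] <- refs$toxicity[[m]] * c_i / refs$standard[[m]]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], metal = m, index_name = "P_single",
        value = p[[m]])
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], metal = m, index_name = "Er",
        value = e[[m]])
    }
    pn <- if (dialect == "rms") sqrt((mean(p)^2 + max(p)^2) / 2) else (mean(p) + max(p)) / 2
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = samples$sample_id[i], metal = NA_character_,
      index_name = "P_N", value = pn)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = samples$sample_id[i], metal = NA_character_,
      index_name = "PERI", value = sum(e))
  }
  do.call(rbind, rows)
}
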