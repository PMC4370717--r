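# Independent brute-force oracles: plain-loop reimplementations of each
# statistic, kept deliberately naive and separate from the package internals.

oracle_cv <- function(x, sample_sd = TRUE) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  s <- sqrt(ss / (if (sample_sd) n - 1 else n))
  s / m
}

oracle_weighted_mean <- function(values, weights) {
  num <- 0; den <- 0
  for (i in seq_along(values)) {
    num <- num + values[i] * weights[i]
    den <- den + weights[i]
  }
  unname(num / den)
}

oracle_community_index <- function(abund, trait_values) {
  tot <- 0
  for (a in abund) tot <- tot + a
  out <- 0
  for (i in seq_along(abund)) out <- out + abund[i] / tot * trait_values[i]
  unname(out)
}

oracle_shannon <- function(p) {
  s <- sum(p)
  h <- 0
  for (v in p) if (v > 0) h <- h - (v / s) * log(v / s)
  h
}

oracle_ic_per_ha <- function(farms, years, eligible) {
  sars <- sort(unique(farms$sar_id))
  out <- numeric(0)
  cost_cols <- c("fertilizers", "feedstuff", "pesticides", "seeds", "fuel",
                 "veterinary", "irrigation")
  for (s in sars) {
    ratios <- c()
    for (y in years) {
      cost <- 0; area <- 0
      for (i in seq_len(nrow(farms))) {
        if (farms$sar_id[i] == s && farms$year[i] == y &&
            farms$production_type[i] %in% eligible) {
          for (cc in cost_cols) cost <- cost + farms[[cc]][i]
          area <- area + farms$utilised_area[i]
        }
      }
      if (area > 0) ratios <- c(ratios, cost / area)
    }
    if (length(ratios)) out[s] <- mean(ratios)
  }
  out
}

oracle_aggregation_index <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      num <- num + w[i, j] * x[j]
      den <- den + w[i, j]
    }
    if (den > 0) out[i] <- x[i] - num / den
  }
  names(out) <- names(x)
  out
}

oracle_morans_i <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- 0; num <- 0; den <- 0
  for (i in seq_len(n)) {
    den <- den + z[i]^2
    for (j in seq_len(n)) {
      s0 <- s0 + w[i, j]
      num <- num + w[i, j] * z[i] * z[j]
    }
  }
  unname((n / s0) * num / den)
}

# random symmetric binary weight matrix with at least one edge
random_weights <- function(n, p = 0.3) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- rbinom(n * (n - 1) / 2, 1, p)
  w <- w + t(w)
  if (sum(w) == 0) w[1, 2] <- w[2, 1] <- 1
  dimnames(w) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  w
}

# small random farm table over a few SARs and years
random_farms <- function(n_sar = 4, n_farm = 3, years = 2004:2006) {
  types <- c("industrial crops", "cereals", "bovine dairy", "bovine meat",
             "mixed", "wine", "vegetables")
  g <- expand.grid(sar = seq_len(n_sar), farm = seq_len(n_farm), year = years)
  costs <- matrix(runif(nrow(g) * 7, 0, 5e4), ncol = 7,
                  dimnames = list(NULL, c("fertilizers", "feedstuff",
                                          "pesticides", "seeds", "fuel",
                                          "veterinary", "irrigation")))
  data.frame(farm_id = paste0("f", g$sar, "_", g$farm),
             sar_id = paste0("sar", g$sar),
             production_type = sample(types, nrow(g), replace = TRUE),
             year = g$year, costs,
             utilised_area = runif(nrow(g), 20, 200),
             stringsAsFactors = FALSE)
}
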