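# Independent oracles and fixture builders used across the suite.
# Deliberately written with plain loops and base R, independent of the
# package's own code paths.

# brute-force re-evaluation of all four signal-quality rules
oracle_filter_report <- function(data, metadata, snr_min = 3,
                                 presence_min = 0.5, r_min = 0.75) {
  study <- metadata$sample_id[metadata$role == "study"]
  blanks <- metadata$sample_id[metadata$role == "blank"]
  qc <- metadata[metadata$role == "qc", , drop = FALSE]
  keys <- unique(data.frame(channel = data$channel,
                            variable = data$variable))
  keys <- keys[order(keys$channel, keys$variable), , drop = FALSE]
  out <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    ch <- keys$channel[k]
    v <- keys$variable[k]
    val <- function(sid) {
      hit <- data$intensity[data$sample_id == sid & data$channel == ch &
                              data$variable == v]
      if (length(hit) == 0) NA_real_ else hit[1]
    }
    sv <- vapply(study, val, numeric(1))
    sv[!is.na(sv) & sv == 0] <- NA  # zero rule acts per cell
    s <- if (all(is.na(sv))) {
      NA_real_
    } else {
      bv <- vapply(blanks, val, numeric(1))
      bv[is.na(bv)] <- 0
      bm <- if (length(bv) == 0) 0 else sum(bv) / length(bv)
      if (bm == 0) Inf else mean(sv[!is.na(sv)]) / bm
    }
    pres <- sum(!is.na(sv)) / length(sv)
    qv <- vapply(qc$sample_id, val, numeric(1))
    qv[is.na(qv)] <- 0
    r <- if (stats::sd(qv) == 0) NA_real_ else stats::cor(qv, qc$dilution)
    rule <- NA_character_
    if (!is.na(s) && s < snr_min) {
      rule <- "snr"
    } else if (pres < presence_min) {
      rule <- "presence"
    } else if (is.na(r) || r <= r_min) {
      rule <- "linearity"
    }
    out[[k]] <- data.frame(variable = v, channel = ch, kept = is.na(rule),
                           first_failing_rule = rule, snr = s,
                           presence_fraction = pres, qc_r = r)
  }
  do.call(rbind, out)
}

# closed-form paired t-test (textbook formula + t distribution)
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# closed-form Welch t-test
oracle_welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df = df))
}

# random long-format intensity matrix exercising every filter rule
random_filter_fixture <- function(seed, n_study = 14, n_blank = 3,
                                  n_var = 50) {
  set.seed(seed)
  samples <- c(sprintf("S%02d", seq_len(n_study)),
               sprintf("B%02d", seq_len(n_blank)),
               paste0("Q", c("a", "b", "c")))
  metadata <- data.frame(
    sample_id = samples,
    role = c(rep("study", n_study), rep("blank", n_blank), rep("qc", 3)),
    dilution = c(rep(NA, n_study + n_blank), 0.25, 0.5, 1.0)
  )
  vars <- sprintf("V%02d", seq_len(n_var))
  grid <- expand.grid(sample_id = samples, variable = vars,
                      stringsAsFactors = FALSE)
  role <- metadata$role[match(grid$sample_id, metadata$sample_id)]
  dil <- metadata$dilution[match(grid$sample_id, metadata$sample_id)]
  base <- exp(rnorm(nrow(grid), log(100), 0.5))
  # per-variable regimes to hit each rule
  regime <- sample(c("clean", "low_snr", "sparse", "bad_qc", "flat_qc"),
                   n_var, replace = TRUE)
  reg <- regime[match(grid$variable, vars)]
  intensity <- base
  intensity[role == "blank"] <- base[role == "blank"] * 0.01
  intensity[role == "blank" & reg == "low_snr"] <-
    base[role == "blank" & reg == "low_snr"] * 2
  intensity[role == "qc"] <- base[role == "qc"] * dil[role == "qc"]
  bad <- role == "qc" & reg == "bad_qc"
  intensity[bad] <- base[bad] / dil[bad]
  intensity[role == "qc" & reg == "flat_qc"] <- 42
  drop <- runif(nrow(grid)) < ifelse(reg == "sparse" & role == "study",
                                     0.7, 0.1)
  zero <- runif(nrow(grid)) < 0.08
  intensity[zero] <- 0
  data <- data.frame(sample_id = grid$sample_id, channel = "positive",
                     variable = grid$variable, intensity = intensity)
  data <- data[!drop, , drop = FALSE]
  list(data = tibble::as_tibble(data),
       metadata = tibble::as_tibble(metadata))
}

# tiny deterministic long table + metadata for hand-computed cases
tiny_matrix <- function(values, dilutions = c(0.25, 0.5, 1.0)) {
  # values: named list variable -> named numeric vector by sample id
  rows <- do.call(rbind, lapply(names(values), function(v) {
    data.frame(sample_id = names(values[[v]]), channel = "positive",
               variable = v, intensity = unname(values[[v]]))
  }))
  tibble::as_tibble(rows)
}
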