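#' Plant a tumor copy-number genome with a target percent gLOH
#'
#' Tiles a genome model with integer allele-specific copy-number states:
#' a diploid-heterozygous background (Ci = 2, Mi = 1), LOH intervals
#' (alternating hemizygous loss (1, 0) and copy-neutral LOH (2, 0)) whose
#' total length approximates the requested percent of the genome, and a few
#' non-LOH gains (3, 1) that help purity/ploidy identification. Intervals are
#' kept below 90% of any arm so none triggers the whole-chromosome/arm
#' exclusion.
#'
#' @param genome genome model.
#' @param target_gloh target percent of the genome in LOH (0-100).
#' @param seed integer seed.
#' @param n_gains number of non-LOH gain segments to add (default 2).
#' @param frac_range length of each LOH interval as a fraction of its arm,
#'   drawn uniformly from this range (default `c(0.25, 0.6)`).
#' @return data.frame of planted segments: `chrom`, `start`, `end`
#'   (0-based half-open, tiling each chromosome), `Ci`, `Mi`.
#' @export
#' @examples
#' pl <- plant_segments(default_genome(), 25, seed = 1)
#' planted_gloh(pl, default_genome())$percent_gloh
plant_segments <- function(genome, target_gloh, seed = 1L, n_gains = 2L,
                           frac_range = c(0.25, 0.6)) {
  validate_genome(genome)
  if (!is_num1(target_gloh) || target_gloh < 0 || target_gloh > 100)
    stop_invalid("target_gloh must be in [0, 100]")
  arms <- arm_table(genome)
  gl <- genome_length(genome)
  with_seed(seed, {
    placed <- list() # per-chromosome list of aberrant intervals
    place <- function(Ci, Mi, want_len) {
      # try arms in random length-weighted order until one has room
      ord <- sample(nrow(arms), nrow(arms), prob = arms$length)
      for (k in ord) {
        a <- arms[k, ]
        len <- min(want_len, floor(0.85 * a$length))
        if (len < 1) next
        lo <- a$start + floor(stats::runif(1) * (a$length - len))
        iv <- c(lo, lo + len)
        prev <- placed[[as.character(a$chrom)]]
        ok <- is.null(prev) ||
          all(iv[2] <= prev[, 1] | iv[1] >= prev[, 2])
        if (ok) {
          placed[[as.character(a$chrom)]] <<-
            rbind(prev, cbind(iv[1], iv[2], Ci, Mi))
          return(iv[2] - iv[1])
        }
      }
      0
    }
    loh_target <- target_gloh / 100 * gl
    loh_len <- 0
    state <- 0L
    tries <- 0L
    while (loh_len < loh_target && tries < 200L) {
      tries <- tries + 1L
      st <- if (state %% 2L == 0L) c(1L, 0L) else c(2L, 0L)
      state <- state + 1L
      a_idx <- sample(nrow(arms), 1, prob = arms$length)
      want <- floor(stats::runif(1, frac_range[1], frac_range[2]) *
                      arms$length[a_idx])
      want <- min(want, ceiling(loh_target - loh_len))
      loh_len <- loh_len + place(st[1], st[2], max(want, 1e6))
    }
    for (i in seq_len(n_gains)) {
      a_idx <- sample(nrow(arms), 1, prob = arms$length)
      place(3L, 1L, floor(0.3 * arms$length[a_idx]))
    }
    # tile each chromosome: fill gaps with diploid het
    segs <- lapply(genome$chrom, function(ch) {
      ab <- placed[[as.character(ch)]]
      L <- genome$length[genome$chrom == ch]
      if (is.null(ab)) {
        return(data.frame(chrom = ch, start = 0, end = L, Ci = 2L, Mi = 1L))
      }
      ab <- ab[order(ab[, 1]), , drop = FALSE]
      out <- list()
      cur <- 0
      for (r in seq_len(nrow(ab))) {
        if (ab[r, 1] > cur)
          out[[length(out) + 1L]] <- c(cur, ab[r, 1], 2L, 1L)
        out[[length(out) + 1L]] <- ab[r, ]
        cur <- ab[r, 2]
      }
      if (cur < L) out[[length(out) + 1L]] <- c(cur, L, 2L, 1L)
      m <- do.call(rbind, out)
      data.frame(chrom = ch, start = m[, 1], end = m[, 2],
                 Ci = as.integer(m[, 3]), Mi = as.integer(m[, 4]))
    })
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
  })
}

validate_planted <- function(planted, genome) {
  need <- c("chrom", "start", "end", "Ci", "Mi")
  if (!all(need %in% names(planted)))
    stop_invalid("planted segments need columns chrom, start, end, Ci, Mi")
  if (any(planted$Ci < 0) || any(planted$Mi < 0) ||
      any(planted$Mi > floor(planted$Ci / 2)))
    stop_invalid("planted states must satisfy 0 <= Mi <= floor(Ci/2)")
  for (ch in genome$chrom) {
    s <- planted[planted$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    L <- genome$length[genome$chrom == ch]
    if (nrow(s) == 0L || s$start[1] != 0 || s$end[nrow(s)] != L ||
        (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)])))
      stop_invalid(paste0("planted segments leave gaps on chromosome ", ch))
  }
  invisible(planted)
}

#' Length-weighted mean copy number of a planted genome
#' @param planted planted segment table.
#' @return numeric ploidy (mean copies per locus).
#' @export
planted_ploidy <- function(planted) {
  w <- planted$end - planted$start
  sum(planted$Ci * w) / sum(w)
}

#' Forward-simulate SNP observations for one tumor sample
#'
#' Generates per-site sequencing depth and alternate-allele read counts for a
#' SNP panel over a planted allele-specific copy-number genome, under a
#' tumor-purity mixture model. At a germline-heterozygous site inside a
#' segment with state (Ci, Mi) and purity p, the minor-allele B-allele
#' frequency is `(p*Mi + (1-p)) / (p*Ci + 2*(1-p))`; which of the two alleles
#' is the alternate is randomized per site. Depth scales with the relative
#' copy ratio `(p*Ci + 2*(1-p)) / (p*psi + 2*(1-p))` (psi = length-weighted
#' mean Ci), with log-normal multiplicative noise on the copy ratio
#' (`lr_noise_sd` on the log2 scale) and Poisson read sampling. The reference
#' (process-matched normal) depth is `depth_mean` at every site.
#'
#' @param genome genome model.
#' @param panel SNP panel from [make_snp_panel()].
#' @param planted planted segment table (see [plant_segments()]); must tile
#'   the genome.
#' @param purity tumor purity in (0, 1].
#' @param depth_mean mean sequencing depth at a normal diploid site (> 0).
#' @param seed integer seed.
#' @param lr_noise_sd per-site Gaussian noise SD on the log2 copy ratio
#'   (default 0.15).
#' @return list of class `sim_sample`: `snp_obs` (data.frame `chrom`, `pos`,
#'   `depth`, `alt_count`, `ref_depth`, `het_in_normal`), `purity`,
#'   `ploidy_true`, `planted`, `gloh_true` (percent gLOH of the planted
#'   genome computed by the same scoring formula used by the engine).
#' @export
#' @examples
#' g <- default_genome()
#' s <- simulate_sample(g, make_snp_panel(g, 500, 1),
#'                      plant_segments(g, 20, 1), purity = 0.7,
#'                      depth_mean = 100, seed = 2)
#' s$gloh_true
simulate_sample <- function(genome, panel, planted, purity,
                            depth_mean = 250, seed = 1L, lr_noise_sd = 0.15) {
  validate_genome(genome)
  if (!is_num1(purity) || purity <= 0 || purity > 1)
    stop_invalid("purity must be in (0, 1]")
  if (!is_num1(depth_mean) || depth_mean <= 0)
    stop_invalid("depth_mean must be positive")
  validate_planted(planted, genome)
  psi <- planted_ploidy(planted)
  p <- purity
  q <- 1 - p
  # map each panel site to its planted segment
  idx <- integer(nrow(panel))
  for (ch in unique(panel$chrom)) {
    sel <- panel$chrom == ch
    s <- which(planted$chrom == ch)
    idx[sel] <- s[findInterval(panel$pos[sel], planted$start[s])]
  }
  Ci <- planted$Ci[idx]
  Mi <- planted$Mi[idx]
  denom <- p * Ci + 2 * q
  baf_minor <- ifelse(denom > 0, (p * Mi + q) / denom, 0.5)
  ratio <- denom / (p * psi + 2 * q)
  with_seed(seed, {
    n <- nrow(panel)
    lam <- depth_mean * ratio * 2^stats::rnorm(n, 0, lr_noise_sd)
    depth <- stats::rpois(n, lam)
    flip <- stats::runif(n) < 0.5
    baf_use <- ifelse(flip, 1 - baf_minor, baf_minor)
    alt <- stats::rbinom(n, depth, baf_use)
    obs <- data.frame(chrom = panel$chrom, pos = panel$pos, depth = depth,
                      alt_count = alt, ref_depth = depth_mean,
                      het_in_normal = panel$het_in_normal)
    res <- planted_gloh(planted, genome)
    structure(list(snp_obs = obs, purity = purity, ploidy_true = psi,
                   planted = planted, gloh_true = res$percent_gloh),
              class = "sim_sample")
  })
}

#' Moment-matched log-normal parameters for a target mean and SD
#'
#' @param mean,sd target arithmetic mean and standard deviation on the
#'   percent scale (both > 0).
#' @return list with `mu` and `sigma` (log-scale parameters).
#' @export
#' @examples
#' p <- gloh_lognormal_params(12.9, 6.9)
#' exp(p$mu + p$sigma^2 / 2)  # 12.9
gloh_lognormal_params <- function(mean, sd) {
  if (!is_num1(mean) || mean <= 0 || !is_num1(sd) || sd < 0)
    stop_invalid("mean must be > 0 and sd >= 0")
  s2 <- log1p((sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

alt_key <- function(gene, alt_class) paste0(gene, ":", alt_class)

#' Valid alteration classes
#' @export
alteration_classes <- function() {
  c("amplification", "homozygous_deletion", "rearrangement",
    "truncation", "missense")
}

default_alteration_table <- function() {
  # Planted generative model: univariate effect sizes (gLOH percentage
  # points) and prevalences of the eight signature alterations, plus
  # zero-effect HR-pathway mutations and uterine-differential alterations
  # that give the group and prevalence analyses realistic structure.
  tab <- rbind(
    data.frame(gene = "FBXW7",  alt_class = "amplification",       prevalence = 0.005, effect = 18.75),
    data.frame(gene = "NF1",    alt_class = "homozygous_deletion", prevalence = 0.012, effect = 10.67),
    data.frame(gene = "BRCA2",  alt_class = "homozygous_deletion", prevalence = 0.021, effect = 6.13),
    data.frame(gene = "RB1",    alt_class = "homozygous_deletion", prevalence = 0.311, effect = 1.90),
    data.frame(gene = "CDKN2A", alt_class = "homozygous_deletion", prevalence = 0.071, effect = 3.13),
    data.frame(gene = "CDKN2B", alt_class = "homozygous_deletion", prevalence = 0.059, effect = 3.11),
    data.frame(gene = "MYC",    alt_class = "amplification",       prevalence = 0.018, effect = 5.44),
    data.frame(gene = "DAXX",   alt_class = "homozygous_deletion", prevalence = 0.005, effect = 9.54),
    data.frame(gene = "RAD51B", alt_class = "homozygous_deletion", prevalence = 0.023, effect = 0),
    data.frame(gene = "ATM",    alt_class = "missense",            prevalence = 0.030, effect = 0),
    data.frame(gene = "BRCA1",  alt_class = "truncation",          prevalence = 0.015, effect = 0),
    data.frame(gene = "CHEK2",  alt_class = "missense",            prevalence = 0.015, effect = 0),
    data.frame(gene = "ATRX",   alt_class = "missense",            prevalence = 0.17,  effect = 0),
    data.frame(gene = "RB1",    alt_class = "truncation",          prevalence = 0.19,  effect = 0),
    data.frame(gene = "TP53",   alt_class = "missense",            prevalence = 0.40,  effect = 0)
  )
  tab$prev_uterine <- NA_real_
  tab$prev_nonuterine <- NA_real_
  # uterine-differential prevalences (uLMS-enriched ATRX mutation,
  # non-uLMS-enriched RB1 mutation)
  tab[tab$gene == "ATRX", c("prev_uterine", "prev_nonuterine")] <- c(0.30, 0.12)
  tab[tab$gene == "RB1" & tab$alt_class == "truncation",
      c("prev_uterine", "prev_nonuterine")] <- c(0.10, 0.25)
  tab
}

#' Cohort simulation specification
#'
#' Bundles the generative model for a synthetic cohort: a log-normal baseline
#' gLOH distribution (moment-matched to a target mean/SD on the percent
#' scale), additive gLOH shifts for planted gene alterations and uterine
#' disease, per-stratum alteration prevalences, and a survival model for the
#' clinical sub-cohort.
#'
#' @param n_samples cohort size (default 1658).
#' @param uterine_fraction fraction of uterine-primary samples (default 0.393).
#' @param gloh_mean,gloh_sd target mean/SD of the baseline gLOH distribution
#'   (default 12.9 / 6.9 percent); converted to log-normal `mu`, `sigma` by
#'   moment matching. Ignored if `mu`/`sigma` given directly.
#' @param mu,sigma optional log-scale parameters overriding the targets.
#' @param alterations data.frame with columns `gene`, `alt_class`,
#'   `prevalence`, `effect` (additive gLOH shift in percentage points) and
#'   optional `prev_uterine`/`prev_nonuterine` per-stratum prevalences.
#' @param uterine_effect additive gLOH shift for uterine samples
#'   (default 0.86).
#' @param exclusive_pairs optional list of 2-element character vectors of
#'   alteration keys ("GENE:class") forced mutually exclusive: when both are
#'   drawn in a sample, one is kept at random.
#' @param survival list: `n` (sub-cohort size, default 40), `baseline_hazard`
#'   (events/month for the gLOH-low group, default log(2)/36, i.e. 36-month
#'   median), `hr_high` (hazard ratio of the gLOH-high group, default 0.31),
#'   `censoring_rate` (probability a record is censored, default 0.3).
#' @param seed integer seed.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1658L, uterine_fraction = 0.393,
                        gloh_mean = 12.9, gloh_sd = 6.9,
                        mu = NULL, sigma = NULL,
                        alterations = default_alteration_table(),
                        uterine_effect = 0.86,
                        exclusive_pairs = NULL,
                        survival = list(), seed = 1L) {
  if (is.null(mu) || is.null(sigma)) {
    pr <- gloh_lognormal_params(gloh_mean, gloh_sd)
    mu <- mu %||% pr$mu
    sigma <- sigma %||% pr$sigma
  }
  surv <- utils::modifyList(
    list(n = 40L, baseline_hazard = log(2) / 36, hr_high = 0.31,
         censoring_rate = 0.3), survival)
  spec <- structure(list(
    n_samples = as.integer(n_samples), uterine_fraction = uterine_fraction,
    mu = mu, sigma = sigma, alterations = alterations,
    uterine_effect = uterine_effect, exclusive_pairs = exclusive_pairs,
    survival = surv, seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  a <- spec$alterations
  prevs <- c(a$prevalence, a$prev_uterine[!is.na(a$prev_uterine)],
             a$prev_nonuterine[!is.na(a$prev_nonuterine)],
             spec$uterine_fraction)
  if (any(prevs < 0 | prevs > 1))
    stop_invalid("prevalences and fractions must lie in [0, 1]")
  if (!is_num1(spec$sigma) || spec$sigma <= 0)
    stop_invalid("sigma must be > 0")
  if (spec$n_samples < 1L) stop_invalid("n_samples must be >= 1")
  if (!all(a$alt_class %in% alteration_classes()))
    stop_invalid("unknown alteration class in spec")
  invisible(spec)
}

#' Simulate a cohort of per-sample gLOH scores and alteration indicators
#'
#' Draws, per sample: uterine status, sex, age, TMB and MSI metadata; binary
#' alteration indicators (independent Bernoulli at the configured prevalence,
#' stratified by uterine status where per-stratum prevalences are given, with
#' optional pairwise exclusivity constraints); and
#' `gLOH = clamp(LogNormal(mu, sigma) + sum(planted effects) +
#' uterine_effect * uterine, 0, 100)`.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `lms_cohort`: `samples` (data.frame `sample`,
#'   `gloh`, `uterine`, `sex`, `age`, `tmb`, `msi`), `alterations` (binary
#'   matrix, one column per "GENE:class" key), `spec`.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n_samples = 200, seed = 42))
#' mean(co$samples$gloh)
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_samples
    uterine <- stats::runif(n) < spec$uterine_fraction
    sex <- ifelse(stats::runif(n) < 0.803, "female", "male")
    age <- stats::rnorm(n, 58, 11.9)
    while (any(bad <- age < 19 | age > 85))
      age[bad] <- stats::rnorm(sum(bad), 58, 11.9)
    tmb <- round(stats::rlnorm(n, 0.21, 1.15), 1)
    msi <- sample(c("high", "stable", "not_performed"), n, replace = TRUE,
                  prob = c(0.004, 0.991, 0.005))
    a <- spec$alterations
    keys <- alt_key(a$gene, a$alt_class)
    pu <- a$prev_uterine %||% rep(NA_real_, nrow(a))
    pn <- a$prev_nonuterine %||% rep(NA_real_, nrow(a))
    M <- matrix(0L, n, nrow(a), dimnames = list(NULL, keys))
    for (j in seq_len(nrow(a))) {
      pj <- if (!is.na(pu[j])) ifelse(uterine, pu[j], pn[j])
            else rep(a$prevalence[j], n)
      M[, j] <- stats::rbinom(n, 1L, pj)
    }
    for (pair in spec$exclusive_pairs %||% list()) {
      both <- which(M[, pair[1]] == 1L & M[, pair[2]] == 1L)
      if (length(both)) {
        drop1 <- stats::runif(length(both)) < 0.5
        M[both[drop1], pair[1]] <- 0L
        M[both[!drop1], pair[2]] <- 0L
      }
    }
    base <- stats::rlnorm(n, spec$mu, spec$sigma)
    gloh <- clamp(base + as.numeric(M %*% a$effect) +
                    spec$uterine_effect * uterine, 0, 100)
    samples <- data.frame(
      sample = sprintf("LMS-%04d", seq_len(n)), gloh = gloh,
      uterine = uterine, sex = sex, age = age, tmb = tmb, msi = msi)
    structure(list(samples = samples, alterations = M, spec = spec),
              class = "lms_cohort")
  })
}

#' Simulate right-censored survival records for a cohort
#'
#' Event times are exponential with hazard `h0 * HR^x`, where `x` indicates
#' gLOH above the cohort median (strictly). Censoring is independent: an
#' exponential censoring time calibrated so each record is censored with the
#' configured probability.
#'
#' @param cohort an `lms_cohort` or a data.frame with a `gloh` column.
#' @param survival_spec list with `baseline_hazard`, `hr_high`,
#'   `censoring_rate`; defaults to the cohort spec's survival block.
#' @param seed integer seed.
#' @return data.frame of class `survival_records`: `sample`, `time` (months),
#'   `event` (logical), `gloh`, `uterine`, `group` ("low"/"high").
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n_samples = 40, seed = 3))
#' sv <- simulate_survival(co, seed = 3)
#' table(sv$group, sv$event)
simulate_survival <- function(cohort, survival_spec = NULL, seed = 1L) {
  df <- if (inherits(cohort, "lms_cohort")) cohort$samples else cohort
  if (is.null(df) || nrow(df) == 0L) stop_invalid("cohort is empty")
  ss <- survival_spec %||%
    (if (inherits(cohort, "lms_cohort")) cohort$spec$survival else NULL) %||%
    list(baseline_hazard = log(2) / 36, hr_high = 0.31, censoring_rate = 0.3)
  h0 <- ss$baseline_hazard
  hr <- ss$hr_high
  cr <- ss$censoring_rate %||% 0
  if (!is_num1(h0) || h0 <= 0) stop_invalid("baseline hazard must be positive")
  if (!is_num1(hr) || hr <= 0) stop_invalid("hazard ratio must be positive")
  if (cr < 0 || cr > 1) stop_invalid("censoring_rate must be in [0, 1]")
  with_seed(seed, {
    n <- nrow(df)
    x <- df$gloh > stats::median(df$gloh)
    h <- h0 * hr^x
    tev <- stats::rexp(n, h)
    if (cr >= 1) {
      time <- tev; event <- rep(FALSE, n)
    } else if (cr <= 0) {
      time <- tev; event <- rep(TRUE, n)
    } else {
      cens <- stats::rexp(n, h * cr / (1 - cr))
      time <- pmin(tev, cens)
      event <- tev <= cens
    }
    out <- data.frame(sample = df$sample %||% sprintf("S%04d", seq_len(n)),
                      time = time, event = event, gloh = df$gloh,
                      uterine = df$uterine %||% rep(FALSE, n),
                      group = factor(ifelse(x, "high", "low"),
                                     levels = c("low", "high")))
    class(out) <- c("survival_records", "data.frame")
    out
  })
}
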