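#' Synthetic mtDNA reference sequence
#'
#' A deterministic synthetic stand-in for the rCRS: a fixed ACGT cycle with
#' the three European diagnostic bases pinned to their macrohaplogroup-N
#' values (m.8701A, m.8540T, m.10873T) so that simulated European lineages
#' pass the diagnostic-triplet filter. It is *not* the real NC_012920
#' sequence; it only needs to provide a stable base at every position.
#'
#' @param length sequence length (default the rCRS length, 16569).
#' @return a single character string of \code{length} bases.
#' @export
mt_reference <- function(length = MT_LENGTH) {
  stopifnot(length >= 1)
  bases <- c("A", "C", "G", "T")[(seq_len(length) - 1L) %% 4L + 1L]
  keep <- EURO_DIAGNOSTIC$pos <= length
  bases[EURO_DIAGNOSTIC$pos[keep]] <- EURO_DIAGNOSTIC$allele[keep]
  paste(bases, collapse = "")
}

# reference base at 1-based positions (vectorised), per mt_reference()
ref_base <- function(pos) {
  b <- c("A", "C", "G", "T")[(pos - 1L) %% 4L + 1L]
  hit <- match(pos, EURO_DIAGNOSTIC$pos)
  b[!is.na(hit)] <- EURO_DIAGNOSTIC$allele[hit[!is.na(hit)]]
  b
}

# canonical transition partner, used as the default alternate allele
alt_base <- function(ref) {
  c(A = "G", G = "A", C = "T", T = "C")[ref]
}

#' Define a haplogroup-like clade for simulation
#'
#' A clade is a maternal lineage defined by one or more substitutions on top
#' of its parent's haplotype; carrying the clade multiplies an individual's
#' disease odds by \code{odds_ratio}.
#'
#' @param name clade label (unique within a configuration).
#' @param frequency probability of belonging to this clade *conditional on*
#'   belonging to its parent (sibling frequencies at each level must sum to
#'   at most 1; the remainder stays on the parent background).
#' @param variants data.frame with column \code{pos} (1-based rCRS) and
#'   optionally \code{allele} (alternate base; defaults to the canonical
#'   transition of the reference base). Must be disjoint from all ancestors'.
#' @param odds_ratio per-clade disease odds ratio (> 0; 1 = neutral).
#' @param parent name of the parent clade, or NA for a top-level clade.
#' @return an object of class \code{clade_def}.
#' @export
clade_def <- function(name, frequency, variants, odds_ratio = 1,
                      parent = NA_character_) {
  if (is.numeric(variants)) variants <- data.frame(pos = variants)
  stopifnot(is.data.frame(variants), "pos" %in% names(variants))
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L | variants$pos > MT_LENGTH))
    abort("clade '%s': variant positions must lie in 1..%d", name, MT_LENGTH)
  if (is.null(variants$allele))
    variants$allele <- unname(alt_base(ref_base(variants$pos)))
  if (!is.numeric(frequency) || frequency < 0 || frequency > 1)
    abort("clade '%s': frequency must be in [0,1]", name)
  if (!is.numeric(odds_ratio) || odds_ratio <= 0)
    abort("clade '%s': odds_ratio must be > 0", name)
  structure(list(name = name, parent = parent,
                 variants = variants[, c("pos", "allele")],
                 frequency = frequency, odds_ratio = odds_ratio),
            class = "clade_def")
}

#' Simulation configuration for a haplogroup-structured case-control cohort
#'
#' @param clades list of \code{\link{clade_def}} objects (possibly nested via
#'   \code{parent}); may be empty.
#' @param n_cases,n_controls target cohort sizes (>= 1).
#' @param n_neutral_snps number of neutral (no disease effect) SNPs whose
#'   minor-allele frequencies are drawn uniformly on \code{neutral_maf_range}.
#' @param neutral_maf_range length-2 numeric in (0, 0.5].
#' @param snp_missing_rate,individual_missing_rate per-call missingness
#'   components in [0, 1); combined per call as
#'   \code{1 - (1 - snp)(1 - individual)}.
#' @param phenotype_missing_rate probability a phenotype is masked to the
#'   missing code, in [0, 1).
#' @param baseline_odds disease odds for the clade-free background (> 0).
#' @param seed integer RNG seed; the whole simulation is deterministic in it.
#' @param draw_cap_mult retrospective sampling aborts after
#'   \code{draw_cap_mult * (n_cases + n_controls)} draws.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(clades = list(), n_cases, n_controls,
                       n_neutral_snps = 0L,
                       neutral_maf_range = c(0.05, 0.4),
                       snp_missing_rate = 0,
                       individual_missing_rate = 0,
                       phenotype_missing_rate = 0,
                       baseline_odds = 1,
                       seed = 1L,
                       draw_cap_mult = 1000L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_neutral_snps >= 0)
  rates <- c(snp_missing_rate, individual_missing_rate, phenotype_missing_rate)
  if (any(rates < 0 | rates >= 1)) abort("missingness rates must lie in [0,1)")
  if (baseline_odds <= 0) abort("baseline_odds must be > 0")
  stopifnot(length(neutral_maf_range) == 2,
            neutral_maf_range[1] > 0, neutral_maf_range[2] <= 0.5,
            neutral_maf_range[1] <= neutral_maf_range[2])
  cfg <- structure(list(
    clades = clades, n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_neutral_snps = as.integer(n_neutral_snps),
    neutral_maf_range = neutral_maf_range,
    snp_missing_rate = snp_missing_rate,
    individual_missing_rate = individual_missing_rate,
    phenotype_missing_rate = phenotype_missing_rate,
    baseline_odds = baseline_odds, seed = as.integer(seed),
    draw_cap_mult = as.integer(draw_cap_mult)), class = "sim_config")
  enumerate_lineages(clades)  # validates nesting, frequencies, disjointness
  cfg
}

# Enumerate terminal lineages of the clade forest. Each lineage is a clade
# together with all its ancestors, terminating there (not descending into any
# child). Returns a data.frame-like list with, per lineage: member clade
# names, marginal probability, summed log odds-ratio, and variant rows.
enumerate_lineages <- function(clades) {
  if (length(clades) == 0) {
    return(list(list(name = "background", clades = character(0),
                     prob = 1, log_or = 0,
                     variants = data.frame(pos = integer(0),
                                           allele = character(0)))))
  }
  names(clades) <- vapply(clades, `[[`, "", "name")
  if (anyDuplicated(names(clades))) abort("duplicate clade names")
  parents <- vapply(clades, `[[`, "", "parent")
  unknown <- parents[!is.na(parents) & !(parents %in% names(clades))]
  if (length(unknown)) abort("unknown parent clade: %s", unknown[1])
  children_of <- function(p) {
    if (is.na(p)) names(clades)[is.na(parents)]
    else names(clades)[!is.na(parents) & parents == p]
  }
  # ancestors' variants must be disjoint from the clade's own
  anc_positions <- function(nm) {
    out <- integer(0)
    p <- clades[[nm]]$parent
    while (!is.na(p)) { out <- c(out, clades[[p]]$variants$pos); p <- clades[[p]]$parent }
    out
  }
  for (nm in names(clades)) {
    if (any(clades[[nm]]$variants$pos %in% anc_positions(nm)))
      abort("clade '%s': defining variants overlap an ancestor's", nm)
  }
  out <- list()
  recurse <- function(node, path, prob, log_or, vars) {
    kids <- children_of(node)
    fsum <- if (length(kids)) sum(vapply(clades[kids], `[[`, 0, "frequency")) else 0
    if (fsum > 1 + 1e-12)
      abort("sibling clade frequencies under '%s' sum to %.3f > 1",
            ifelse(is.na(node), "(root)", node), fsum)
    # terminal mass: stay on this background
    out[[length(out) + 1L]] <<- list(
      name = ifelse(is.na(node), "background", node),
      clades = path, prob = prob * (1 - fsum), log_or = log_or,
      variants = vars)
    for (k in kids) {
      cl <- clades[[k]]
      recurse(k, c(path, k), prob * cl$frequency, log_or + log(cl$odds_ratio),
              rbind(vars, cl$variants))
    }
  }
  recurse(NA_character_, character(0), 1, 0,
          data.frame(pos = integer(0), allele = character(0)))
  out
}

#' Simulate a haplogroup-structured mtDNA case-control cohort
#'
#' Retrospective (case-control) sampling: individuals are drawn one at a
#' time — a clade lineage by its population frequency, a haplotype as the
#' union of the lineage's defining alternate alleles plus neutral alleles at
#' their MAFs — and labelled a case with probability
#' \code{plogis(log(baseline_odds) + sum(log(OR_clade)))}. Draws continue
#' until exactly \code{n_cases} cases and \code{n_controls} controls have
#' accrued (extras of a filled stratum are discarded, matching case-control
#' ascertainment). Missingness is then applied via
#' \code{\link{apply_missingness}}. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{genotype_table}} with attribute \code{"truth"}
#'   (per-individual lineage and the id of each clade-defining SNP).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lineages <- enumerate_lineages(config$clades)
  lin_prob <- vapply(lineages, `[[`, 0, "prob")
  lin_pcase <- stats::plogis(log(config$baseline_odds) +
                             vapply(lineages, `[[`, 0, "log_or"))

  clade_vars <- unique(do.call(rbind, lapply(lineages, `[[`, "variants")))
  clade_vars <- clade_vars[order(clade_vars$pos), , drop = FALSE]
  if (anyDuplicated(clade_vars$pos))
    abort("two clades define different alleles at the same position")
  n_clade_snps <- nrow(clade_vars)

  neutral_pos <- sort(sample(setdiff(seq_len(MT_LENGTH), clade_vars$pos),
                             config$n_neutral_snps))
  neutral_maf <- stats::runif(config$n_neutral_snps,
                              config$neutral_maf_range[1],
                              config$neutral_maf_range[2])

  # per-lineage clade-SNP template (0/1 over clade_vars rows)
  templates <- vapply(lineages, function(ln)
    as.integer(clade_vars$pos %in% ln$variants$pos), integer(n_clade_snps))
  templates <- matrix(templates, nrow = n_clade_snps)

  quota <- c(cases = config$n_cases, controls = config$n_controls)
  cap <- config$draw_cap_mult * (config$n_cases + config$n_controls)
  kept_lin <- integer(0); kept_case <- logical(0)
  kept_neutral <- matrix(integer(0), nrow = 0, ncol = config$n_neutral_snps)
  got <- c(cases = 0L, controls = 0L); drawn <- 0L
  batch <- max(1024L, config$n_cases + config$n_controls)
  while (got["cases"] < quota["cases"] || got["controls"] < quota["controls"]) {
    if (drawn >= cap)
      abort(paste0("retrospective sampling cap exceeded (%d draws): got %d/%d",
                   " cases and %d/%d controls; check baseline_odds and ORs"),
            drawn, got["cases"], quota["cases"], got["controls"], quota["controls"])
    b <- min(batch, cap - drawn)
    lin <- sample.int(length(lineages), b, replace = TRUE, prob = lin_prob)
    case <- stats::runif(b) < lin_pcase[lin]
    neut <- if (config$n_neutral_snps > 0)
      matrix(stats::rbinom(b * config$n_neutral_snps, 1L,
                           rep(neutral_maf, each = b)),
             nrow = b, ncol = config$n_neutral_snps)
      else matrix(integer(0), nrow = b, ncol = 0)
    drawn <- drawn + b
    # keep in draw order until each stratum's quota fills
    need_case <- cumsum(case) <= (quota["cases"] - got["cases"])
    need_ctl  <- cumsum(!case) <= (quota["controls"] - got["controls"])
    keep <- (case & need_case) | (!case & need_ctl)
    kept_lin  <- c(kept_lin, lin[keep])
    kept_case <- c(kept_case, case[keep])
    kept_neutral <- rbind(kept_neutral, neut[keep, , drop = FALSE])
    got <- c(cases = sum(kept_case), controls = sum(!kept_case))
  }

  n <- length(kept_lin)
  geno_clade <- t(templates[, kept_lin, drop = FALSE])
  geno <- cbind(geno_clade, kept_neutral)
  pos  <- c(clade_vars$pos, neutral_pos)
  refs <- ref_base(pos)
  alts <- c(clade_vars$allele,
            if (config$n_neutral_snps > 0) unname(alt_base(ref_base(neutral_pos))))
  ord  <- order(pos)
  snp_meta <- data.frame(id = sprintf("mt%d", pos[ord]), pos = pos[ord],
                         ref = refs[ord], alt = alts[ord],
                         stringsAsFactors = FALSE)
  g <- genotype_table(geno[, ord, drop = FALSE],
                      sample_ids = sprintf("S%05d", seq_len(n)),
                      phenotype  = ifelse(kept_case, 2L, 1L),
                      snp_meta   = snp_meta)
  g <- apply_missingness(g, config)
  attr(g, "truth") <- list(
    lineage = vapply(lineages[kept_lin], `[[`, "", "name"),
    clade_snp_ids = sprintf("mt%d", clade_vars$pos))
  g
}

#' Apply genotype and phenotype missingness to a cohort
#'
#' Each genotype call is independently set missing with probability
#' \code{1 - (1 - snp_missing_rate)(1 - individual_missing_rate)}; each
#' phenotype is masked with probability \code{phenotype_missing_rate}.
#' Uses the current RNG stream (seeded by \code{\link{simulate_cohort}}).
#'
#' @param g a \code{\link{genotype_table}}.
#' @param config a \code{\link{sim_config}} supplying the three rates.
#' @return the masked \code{genotype_table}; attribute
#'   \code{"missingness_applied"} counts masked genotype calls and phenotypes.
#' @export
apply_missingness <- function(g, config) {
  p_call <- 1 - (1 - config$snp_missing_rate) * (1 - config$individual_missing_rate)
  n_geno_masked <- 0L
  if (p_call > 0) {
    mask <- matrix(stats::runif(length(g$geno)) < p_call, nrow = nrow(g$geno))
    n_geno_masked <- sum(mask & !is.na(g$geno))
    g$geno[mask] <- NA_integer_
  }
  n_phen_masked <- 0L
  if (config$phenotype_missing_rate > 0) {
    pm <- stats::runif(n_samples(g)) < config$phenotype_missing_rate
    n_phen_masked <- sum(pm & !is.na(g$phenotype))
    g$phenotype[pm] <- NA_integer_
  }
  attr(g, "missingness_applied") <-
    c(genotype_calls = n_geno_masked, phenotypes = n_phen_masked)
  g
}

#' Simulate an aligned mtDNA sequence panel
#'
#' Generates equal-length uppercase sequences from the synthetic reference
#' (\code{\link{mt_reference}}) by applying clade-defining substitutions to
#' lineages drawn at the clade frequencies. To exercise downstream panel
#' filters, a fraction of sequences can be truncated (to lengths in
#' \code{truncate_range}) and a fraction given a non-European diagnostic
#' allele (m.8701G).
#'
#' @param n_sequences number of sequences.
#' @param clades list of \code{\link{clade_def}} objects.
#' @param length full sequence length (default rCRS length).
#' @param seed integer RNG seed.
#' @param truncated_fraction,non_european_fraction probabilities in [0, 1).
#' @param truncate_range integer range the truncated lengths are drawn from.
#' @param private_variant_rate expected number of additional private
#'   (sequence-specific, hence rare) substitutions per sequence, drawn
#'   Poisson at uniform positions; 0 disables them, so a clade-free panel
#'   reproduces the reference exactly.
#' @return a \code{\link{sequence_panel}}.
#' @export
simulate_panel <- function(n_sequences, clades = list(), length = MT_LENGTH,
                           seed = 1L, truncated_fraction = 0,
                           non_european_fraction = 0,
                           truncate_range = c(15000L, 16499L),
                           private_variant_rate = 0) {
  stopifnot(length >= 1, n_sequences >= 1)
  all_pos <- unlist(lapply(clades, function(cl) cl$variants$pos))
  if (any(all_pos > length)) abort("clade variant position beyond sequence length")
  set.seed(seed)
  reference <- mt_reference(length)
  lineages <- enumerate_lineages(clades)
  lin <- sample.int(length(lineages), n_sequences, replace = TRUE,
                    prob = vapply(lineages, `[[`, 0, "prob"))
  seqs <- vapply(lineages[lin], function(ln) {
    s <- reference
    if (nrow(ln$variants))
      for (i in seq_len(nrow(ln$variants)))
        substr(s, ln$variants$pos[i], ln$variants$pos[i]) <- ln$variants$allele[i]
    s
  }, "")
  if (private_variant_rate > 0) {
    # avoid perturbing the diagnostic triplet: private variants must not
    # masquerade as non-European lineage markers
    safe <- setdiff(seq_len(length), EURO_DIAGNOSTIC$pos)
    for (i in seq_len(n_sequences)) {
      k <- stats::rpois(1, private_variant_rate)
      if (k > 0) {
        at <- sample(safe, k)
        for (p in at) {
          cur <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- alt_base(cur)
        }
      }
    }
  }
  if (non_european_fraction > 0) {
    hit <- stats::runif(n_sequences) < non_european_fraction
    for (i in which(hit)) substr(seqs[i], 8701, 8701) <- "G"
  }
  if (truncated_fraction > 0) {
    hit <- stats::runif(n_sequences) < truncated_fraction
    lens <- sample(seq(truncate_range[1], min(truncate_range[2], length - 1L)),
                   sum(hit), replace = TRUE)
    seqs[hit] <- substr(seqs[hit], 1L, lens)
  }
  names(seqs) <- sprintf("seq%05d", seq_len(n_sequences))
  sequence_panel(seqs, reference = reference)
}
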