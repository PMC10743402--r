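#' Default consensus method panel
#'
#' The nine prediction methods whose calls gate consensus VUS selection by
#' default: the eight dbNSFP-derived methods with high balanced accuracy on
#' curated OTOF variants plus SAV-Pred. Each entry carries the cutoff and
#' direction used to derive pathogenic/benign calls from raw scores. The
#' mean rank-score panel is these nine plus ConStruct itself.
#'
#' @return list of method configs (`name`, `cutoff`, `direction`)
#' @export
default_method_panel <- function() {
  lapply(c("MetaLR", "MetaSVM", "MutationAssessor", "PolyPhen2_HDIV",
           "PROVEAN", "SIFT4G", "MutPred", "LIST_S2", "SAV_Pred"),
         function(nm) list(name = nm, cutoff = 0.5,
                           direction = "higher_is_pathogenic"))
}

#' Simulation configuration
#'
#' Bundles every distributional assumption of the synthetic-data generator
#' in one place. Defaults emulate a curated OTOF missense set: 93
#' pathogenic / 177 benign training variants and 1302 VUS, with the
#' class-conditional tendencies of such data — pathogenic variants enriched
#' in C2 domains 2-7 (and hence in high-numbered exons), carrying
#' negative-BLOSUM80 substitutions and high phyloP conservation; benign
#' variants spread uniformly with conservation near zero and conservative
#' substitutions.
#'
#' @param n_pathogenic,n_benign,n_vus set sizes (defaults 93, 177, 1302)
#' @param seed integer RNG seed
#' @param domain_enrichment probability a pathogenic variant falls inside
#'   `enriched_domains` (default 0.8)
#' @param enriched_domains domain codes pathogenic variants favour
#' @param phylop100_pathogenic,phylop100_benign `c(mean, sd)` of the
#'   100-vertebrate phyloP per class (defaults N(6, 1.5) vs N(0, 1.5),
#'   phyloP units)
#' @param phylop30_pathogenic,phylop30_benign same for the 30-primate
#'   track (defaults N(0.6, 0.3) vs N(0, 0.3))
#' @param blosum_weight substitution sampling weight: alternates are drawn
#'   with probability proportional to `exp(-w * score)` for pathogenic and
#'   `exp(+w * score)` for benign (default 0.6)
#' @param n_planted number of VUS planted as clear consensus positives
#'   (default 16)
#' @param planted_phylop100,planted_phylop30 `c(mean, sd)` for planted VUS
#'   conservation (strong-signal profile)
#' @param planted_blosum_weight substitution weight for planted VUS
#' @param vus_latent_planted,vus_latent_background `c(mean, sd)` of the
#'   shared latent pathogenicity driving per-method scores
#' @param method_noise_sd per-method noise on the latent (controls method
#'   concordance)
#' @param method_missingness per-entry probability a method score is
#'   missing
#' @param methods method panel, default [default_method_panel()]
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(n_pathogenic = 93, n_benign = 177,
                              n_vus = 1302, seed = 17,
                              domain_enrichment = 0.8,
                              enriched_domains = 2:7,
                              phylop100_pathogenic = c(6, 1.5),
                              phylop100_benign = c(0, 1.5),
                              phylop30_pathogenic = c(0.6, 0.3),
                              phylop30_benign = c(0, 0.3),
                              blosum_weight = 0.6,
                              n_planted = 16,
                              planted_phylop100 = c(7, 0.8),
                              planted_phylop30 = c(0.8, 0.15),
                              planted_blosum_weight = 1.2,
                              vus_latent_planted = c(2.5, 0.3),
                              vus_latent_background = c(-2, 1),
                              method_noise_sd = 0.5,
                              method_missingness = 0,
                              methods = default_method_panel()) {
  cfg <- as.list(environment())
  stopifnot(n_pathogenic >= 0, n_benign >= 0, n_vus >= 0, n_planted >= 0,
            domain_enrichment >= 0, domain_enrichment <= 1,
            method_missingness >= 0, method_missingness <= 1)
  structure(cfg, class = "simulation_config")
}

STANDARD_AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]

# alt residues drawn with probability ~ exp(-weight * blosum score):
# positive weight favours disruptive (negative-score) substitutions
sample_substitutions <- function(n, weight, matrix) {
  ref <- sample(STANDARD_AA, n, replace = TRUE)
  alt <- vapply(ref, function(r) {
    others <- setdiff(STANDARD_AA, r)
    s <- blosum_score(rep(r, length(others)), others, matrix)
    sample(others, 1L, prob = exp(-weight * s))
  }, character(1L))
  data.frame(ref_aa = ref, alt_aa = unname(alt))
}

# per-residue position weights with total mass `enrichment` inside the
# union of the enriched domains
position_weights <- function(map, enrichment, enriched_domains) {
  L <- map$protein_length
  w <- rep(1 / L, L)
  if (enrichment > 0) {
    dom <- map$domains[map$domains$code %in% enriched_domains, , drop = FALSE]
    if (nrow(dom) == 0L)
      stop("domain enrichment requested but no enriched domains in the map")
    inside <- rep(FALSE, L)
    for (i in seq_len(nrow(dom))) inside[dom$start[i]:dom$end[i]] <- TRUE
    w[inside] <- enrichment / sum(inside)
    w[!inside] <- (1 - enrichment) / sum(!inside)
  }
  w
}

#' Simulate a labelled training set
#'
#' Draws `n_pathogenic + n_benign` single amino-acid variants at distinct
#' positions with the class-conditional structure of the configuration:
#' pathogenic positions concentrated in the enriched C2 domains,
#' substitutions biased toward negative BLOSUM80 scores and high phyloP;
#' benign variants uniform over the sequence with conservative
#' substitutions and low conservation. Output is byte-identical for a
#' given seed and validates against [write_variant_table()] /
#' [read_variant_table()].
#'
#' @param config a [simulation_config()]
#' @param map annotation map
#' @param matrix substitution matrix
#' @return labelled variant data frame (pathogenic rows first)
#' @export
simulate_training_set <- function(config = simulation_config(),
                                  map = otoferlin_annotation(),
                                  matrix = blosum80()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- map$protein_length
  n_p <- config$n_pathogenic; n_b <- config$n_benign
  if (n_p + n_b > L) stop("more variants requested than distinct positions")
  w <- position_weights(map, if (n_p > 0) config$domain_enrichment else 0,
                        config$enriched_domains)
  pos_p <- if (n_p > 0) sample(L, n_p, prob = w) else integer(0)
  pos_b <- if (n_b > 0) sample(setdiff(seq_len(L), pos_p), n_b) else integer(0)
  draw <- function(n, pos, lab, bw, p100, p30) {
    if (n == 0L) return(NULL)
    sub <- sample_substitutions(n, bw, matrix)
    data.frame(position = pos, ref_aa = sub$ref_aa, alt_aa = sub$alt_aa,
               label = lab, rs_id = NA_character_,
               allele_frequency = NA_real_,
               phylop100 = stats::rnorm(n, p100[1], p100[2]),
               phylop30 = stats::rnorm(n, p30[1], p30[2]),
               exon_number = exon_of(pos, map))
  }
  rbind(draw(n_p, pos_p, "pathogenic", config$blosum_weight,
             config$phylop100_pathogenic, config$phylop30_pathogenic),
        draw(n_b, pos_b, "benign", -config$blosum_weight,
             config$phylop100_benign, config$phylop30_benign))
}

#' Simulate a VUS set with per-method scores
#'
#' Draws `n_vus` unlabelled variants, `n_planted` of which carry a clear
#' pathogenic feature profile (the strong-signal planted positives a
#' consensus screen should recover) while the rest follow the benign
#' profile. Per-method raw scores are generated from a shared latent
#' pathogenicity plus independent per-method noise, so method concordance
#' is tunable; calls are derived from each method's cutoff and rank scores
#' are computed locally with [rank_scores_from_raw()].
#'
#' @inheritParams simulate_training_set
#' @return list with `variants` (VUS data frame), `scores` (per-method
#'   score/rankscore/call data frame aligned with `variants`), `planted`
#'   (logical vector marking the planted positives) and `methods` (the
#'   panel config)
#' @export
simulate_vus_set <- function(config = simulation_config(),
                             map = otoferlin_annotation(),
                             matrix = blosum80()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 104729L)  # decoupled stream from the training draw
  L <- map$protein_length
  n <- config$n_vus; k <- min(config$n_planted, n)
  if (n > L) stop("more VUS requested than distinct positions")
  pos_planted <- if (k > 0)
    sample(L, k, prob = position_weights(map, 1, config$enriched_domains))
  else integer(0)
  pos_rest <- sample(setdiff(seq_len(L), pos_planted), n - k)
  planted <- c(rep(TRUE, k), rep(FALSE, n - k))
  pos <- c(pos_planted, pos_rest)
  sub <- rbind(
    if (k > 0) sample_substitutions(k, config$planted_blosum_weight, matrix),
    sample_substitutions(n - k, -config$blosum_weight, matrix))
  rn <- function(n, ms) stats::rnorm(n, ms[1], ms[2])
  variants <- data.frame(
    position = pos, ref_aa = sub$ref_aa, alt_aa = sub$alt_aa,
    label = "vus", rs_id = NA_character_, allele_frequency = NA_real_,
    phylop100 = c(rn(k, config$planted_phylop100),
                  rn(n - k, config$phylop100_benign)),
    phylop30 = c(rn(k, config$planted_phylop30),
                 rn(n - k, config$phylop30_benign)),
    exon_number = exon_of(pos, map))
  latent <- c(rn(k, config$vus_latent_planted),
              rn(n - k, config$vus_latent_background))
  scores <- variants[c("position", "ref_aa", "alt_aa")]
  for (m in config$methods) {
    raw <- stats::plogis(latent + stats::rnorm(n, 0, config$method_noise_sd))
    if (config$method_missingness > 0)
      raw[stats::runif(n) < config$method_missingness] <- NA_real_
    scores[[paste0(m$name, "_score")]] <- raw
    scores[[paste0(m$name, "_rankscore")]] <-
      if (all(is.na(raw))) rep(NA_real_, n) else rank_scores_from_raw(raw)
    scores[[paste0(m$name, "_call")]] <- derive_calls(raw, m)
  }
  list(variants = variants, scores = scores, planted = planted,
       methods = config$methods)
}
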