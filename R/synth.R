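#' Parameters for a synthetic isolate collection
#'
#' Describes a collection of bacterial isolates organized into planted
#' taxonomic groups, observed through noisy technical replicates. Each group
#' owns a pool of protein-region marker masses; a member carries each marker
#' of its own group with probability `protein_within_presence` and each
#' marker of any other group with probability `protein_cross_presence`, so
#' protein fingerprints are highly similar within a group and nearly
#' orthogonal between groups. Small-molecule chemistry is a group core
#' (shared by every member) plus isolate-private accessory masses, giving
#' the partially overlapping per-group metabolite universes the greedy
#' selection operates on. Replicates observe each true peak with probability
#' `1 - replicate_dropout`, jitter its m/z, and add replicate-private noise
#' peaks.
#'
#' @param n_groups number of planted groups.
#' @param isolates_per_group isolates in each group (scalar, or length-2
#'   range sampled uniformly per group).
#' @param n_replicates technical replicates per isolate.
#' @param protein_pool_per_group protein marker masses per group.
#' @param protein_within_presence,protein_cross_presence probabilities that
#'   an isolate carries a marker of its own / another group.
#' @param np_core_per_group small-molecule masses shared by all group
#'   members.
#' @param np_accessory_per_isolate isolate-private small-molecule masses.
#' @param replicate_dropout probability a true peak is missing from one
#'   replicate.
#' @param mz_jitter_sd_protein,mz_jitter_sd_np replicate m/z jitter standard
#'   deviations in Daltons.
#' @param noise_peaks_per_replicate replicate-private spurious peaks, drawn
#'   uniformly over 200-15,000 Da; because they are private to a replicate,
#'   the default 2-of-3 consensus rule removes them in expectation.
#' @param seed integer seed; the whole collection is reproducible from it.
#' @return A validated list of class `"synth_params"`.
#' @export
synth_params <- function(n_groups = 5L, isolates_per_group = 8L,
                         n_replicates = 3L, protein_pool_per_group = 30L,
                         protein_within_presence = 0.9,
                         protein_cross_presence = 0.05,
                         np_core_per_group = 10L,
                         np_accessory_per_isolate = 5L,
                         replicate_dropout = 0.1,
                         mz_jitter_sd_protein = 0.3,
                         mz_jitter_sd_np = 0.03,
                         noise_peaks_per_replicate = 3L,
                         seed = 1L) {
  p <- list(n_groups = as.integer(n_groups),
            isolates_per_group = as.integer(isolates_per_group),
            n_replicates = as.integer(n_replicates),
            protein_pool_per_group = as.integer(protein_pool_per_group),
            protein_within_presence = protein_within_presence,
            protein_cross_presence = protein_cross_presence,
            np_core_per_group = as.integer(np_core_per_group),
            np_accessory_per_isolate = as.integer(np_accessory_per_isolate),
            replicate_dropout = replicate_dropout,
            mz_jitter_sd_protein = mz_jitter_sd_protein,
            mz_jitter_sd_np = mz_jitter_sd_np,
            noise_peaks_per_replicate = as.integer(noise_peaks_per_replicate),
            seed = as.integer(seed))
  probs <- c(p$protein_within_presence, p$protein_cross_presence,
             p$replicate_dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(p$n_groups, p$n_replicates, p$isolates_per_group)
  if (any(counts < 1L)) stop("group, isolate and replicate counts must be >= 1")
  if (any(c(p$protein_pool_per_group, p$np_core_per_group,
            p$np_accessory_per_isolate, p$noise_peaks_per_replicate) < 0L))
    stop("peak counts must be >= 0")
  if (length(p$isolates_per_group) > 2L)
    stop("isolates_per_group must be a scalar or a length-2 range")
  if (p$mz_jitter_sd_protein < 0 || p$mz_jitter_sd_np < 0)
    stop("jitter standard deviations must be >= 0")
  structure(p, class = "synth_params")
}

# Draw n mass values uniform over [low, high] subject to a minimum pairwise
# separation, by sequential rejection.
draw_separated <- function(n, low, high, min_sep) {
  if (n == 0L) return(numeric(0))
  if ((high - low) < n * min_sep)
    stop("region too narrow for ", n, " masses at separation ", min_sep)
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- stats::runif(n - length(out), low, high)
    for (x in cand)
      if (!length(out) || min(abs(out - x)) >= min_sep) out <- c(out, x)
    tries <- tries + 1L
    if (tries > 10000L) stop("failed to place separated masses")
  }
  sort(out)
}

#' Simulate a collection of isolates with planted group structure
#'
#' Generates per-replicate peak lists plus the ground truth needed to score
#' every downstream stage: the planted partition, each isolate's true
#' protein and small-molecule masses, and each group's small-molecule
#' universe. True masses are drawn with a minimum pairwise separation of 5x
#' the default matching tolerance of their region (10 Da protein, 1 Da
#' small-molecule) so that tolerance binning is unambiguous in noise-free
#' settings. Isolate ids (`G1I01`, ...) contain no underscore, so the
#' default `"{isolate}_{replicate}"` spectrum naming pattern stays
#' unambiguous.
#'
#' @param params a [synth_params()] object.
#' @return A list with `peaklists` (one [peaklist] per isolate per
#'   replicate) and `truth`: `assignment` (planted [group_assignment()]),
#'   `protein_mz` and `np_mz` (named per-isolate lists of true masses),
#'   `np_universe` (per-group list of distinct small-molecule masses) and
#'   `params`.
#' @export
simulate_collection <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  ng <- params$n_groups
  sizes <- if (length(params$isolates_per_group) == 2L)
    sample(params$isolates_per_group[1L]:params$isolates_per_group[2L],
           ng, replace = TRUE)
  else rep(params$isolates_per_group, ng)

  # group-level true masses, globally separated within each region
  prot_all <- draw_separated(ng * params$protein_pool_per_group,
                             mass_regions$protein["low"],
                             mass_regions$protein["high"], 10)
  prot_pool <- split(sample(prot_all),
                     rep(seq_len(ng), each = params$protein_pool_per_group))
  n_np <- ng * params$np_core_per_group +
    sum(sizes) * params$np_accessory_per_isolate
  np_all <- sample(draw_separated(n_np, mass_regions$np["low"],
                                  mass_regions$np["high"] - 1e-6, 1))
  np_core <- lapply(seq_len(ng), function(g)
    np_all[(g - 1L) * params$np_core_per_group +
             seq_len(params$np_core_per_group)])
  np_acc_pool <- np_all[-seq_len(ng * params$np_core_per_group)]

  iso_ids <- character(0)
  group_of <- integer(0)
  protein_mz <- list()
  np_mz <- list()
  acc_i <- 0L
  for (g in seq_len(ng)) {
    for (i in seq_len(sizes[g])) {
      id <- sprintf("G%dI%02d", g, i)
      iso_ids <- c(iso_ids, id)
      group_of <- c(group_of, g)
      own <- prot_pool[[g]][stats::runif(length(prot_pool[[g]])) <
                              params$protein_within_presence]
      cross <- unlist(lapply(prot_pool[-g], function(pool)
        pool[stats::runif(length(pool)) < params$protein_cross_presence]))
      acc <- if (params$np_accessory_per_isolate > 0L)
        np_acc_pool[acc_i + seq_len(params$np_accessory_per_isolate)]
      else numeric(0)
      acc_i <- acc_i + params$np_accessory_per_isolate
      protein_mz[[id]] <- unname(sort(c(own, cross)))
      np_mz[[id]] <- sort(c(np_core[[g]], acc))
    }
  }
  names(group_of) <- iso_ids

  # per-true-peak base intensities; replicates scatter around them
  base_int <- lapply(iso_ids, function(id)
    list(protein = stats::rlnorm(length(protein_mz[[id]]), log(50), 0.5),
         np = stats::rlnorm(length(np_mz[[id]]), log(50), 0.5)))
  names(base_int) <- iso_ids

  observe <- function(mz, base, jitter_sd) {
    keep <- stats::runif(length(mz)) >= params$replicate_dropout
    mz <- mz[keep] + stats::rnorm(sum(keep), 0, jitter_sd)
    list(mz = mz, intensity = base[keep] * stats::runif(sum(keep), 0.8, 1.2))
  }

  peaklists <- list()
  for (id in iso_ids) {
    for (r in seq_len(params$n_replicates)) {
      prot <- observe(protein_mz[[id]], base_int[[id]]$protein,
                      params$mz_jitter_sd_protein)
      np <- observe(np_mz[[id]], base_int[[id]]$np, params$mz_jitter_sd_np)
      n_noise <- params$noise_peaks_per_replicate
      noise_mz <- stats::runif(n_noise, mass_regions$np["low"],
                               mass_regions$protein["high"])
      noise_int <- stats::rlnorm(n_noise, log(20), 0.5)
      mz <- c(prot$mz, np$mz, noise_mz)
      inten <- c(prot$intensity, np$intensity, noise_int)
      if (anyDuplicated(mz)) {
        inten <- as.numeric(tapply(inten, mz, max))
        mz <- sort(unique(mz))
      }
      keep <- mz > 0
      peaklists[[paste0(id, "_r", r)]] <-
        peaklist(mz[keep], inten[keep], isolate_id = id,
                 replicate_id = paste0("r", r))
    }
  }

  np_universe <- lapply(seq_len(ng), function(g)
    sort(unique(unlist(np_mz[iso_ids[group_of == g]]))))

  list(peaklists = peaklists,
       truth = list(
         assignment = group_assignment(group_of, cut_mode = "planted",
                                       cut_value = ng),
         protein_mz = protein_mz,
         np_mz = np_mz,
         np_universe = np_universe,
         params = params))
}
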