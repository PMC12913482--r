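# Synthetic phage-host data generator.
#
# Emulates the statistical structure the predictor exploits: hosts are
# organized in a five-rank taxonomy (genus..phylum) whose clades carry
# distinct 3-mer compositional profiles; phage composition is pulled toward
# the true host's clade profile by a single mimicry parameter; labeled
# pairs follow the positive + phylum-exclusion-negative construction.
#
# Clade profiles are Dirichlet draws per phylum, perturbed down the ranks
# (child = inheritance * parent + (1 - inheritance) * fresh Dirichlet), so
# compositional similarity decays with taxonomic distance and rank-level
# accuracy has the expected upward trend from genus to phylum.

#' Configuration for the synthetic generator
#'
#' Defaults are the desk-scale study conditions used throughout the
#' package's own experiments: 4 phyla with one lineage each, two hosts per
#' genus, four phages per host, 20 kb genomes and strong (0.9) phage
#' mimicry of the host clade composition.
#'
#' @param n_phyla number of phyla.
#' @param children_per_node children per taxonomy node at each rank below
#'   phylum (so there are `n_phyla * children_per_node^4` genera).
#' @param hosts_per_genus hosts per genus.
#' @param phages_per_host phages per host.
#' @param host_length,phage_length genome lengths in bp.
#' @param mimicry_strength fraction in [0, 1]: weight of the host clade
#'   profile in the phage's generating mixture (the rest is uniform
#'   background). Controls task difficulty.
#' @param profile_concentration Dirichlet concentration for clade profiles
#'   (smaller = spikier, more distinctive clades).
#' @param rank_inheritance weight of the parent profile when deriving a
#'   child clade's profile.
#' @param seed integer RNG seed.
#' @return a validated `SyntheticConfig` list.
#' @export
syntheticConfig <- function(n_phyla = 4L, children_per_node = 1L,
                            hosts_per_genus = 2L, phages_per_host = 4L,
                            host_length = 20000L, phage_length = 20000L,
                            mimicry_strength = 0.9,
                            profile_concentration = 1.0,
                            rank_inheritance = 0.6, seed = 1L) {
  cfg <- list(n_phyla = n_phyla, children_per_node = children_per_node,
              hosts_per_genus = hosts_per_genus,
              phages_per_host = phages_per_host,
              host_length = host_length, phage_length = phage_length,
              mimicry_strength = mimicry_strength,
              profile_concentration = profile_concentration,
              rank_inheritance = rank_inheritance, seed = as.integer(seed))
  for (nm in c("n_phyla", "children_per_node", "hosts_per_genus",
               "phages_per_host", "host_length", "phage_length"))
    .assertCount(cfg[[nm]], nm)
  if (!is.numeric(mimicry_strength) || mimicry_strength < 0 ||
      mimicry_strength > 1)
    .phnStop("config", "mimicry_strength must lie in [0, 1]")
  if (!is.numeric(profile_concentration) || profile_concentration <= 0)
    .phnStop("config", "profile_concentration must be positive")
  if (!is.numeric(rank_inheritance) || rank_inheritance < 0 ||
      rank_inheritance > 1)
    .phnStop("config", "rank_inheritance must lie in [0, 1]")
  class(cfg) <- c("SyntheticConfig", "list")
  cfg
}

#' Generate a five-rank taxonomy
#'
#' Produces `n_phyla * children_per_node^4` genus-level lineages forming a
#' proper tree: names are prefixed by their parent's name, so two lineages
#' sharing a genus share every coarser rank. Deterministic.
#'
#' @param cfg a [syntheticConfig()].
#' @return data.frame with columns `genus`, `family`, `order`, `class`,
#'   `phylum`, one row per genus.
#' @export
generateTaxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  cpn <- cfg$children_per_node
  out <- data.frame(phylum = sprintf("Phy%02d", seq_len(cfg$n_phyla)))
  labs <- c(class = "Cla", order = "Ord", family = "Fam", genus = "Gen")
  for (rank in names(labs)) {
    nparent <- nrow(out)
    idx <- rep(seq_len(nparent), each = cpn)
    parentName <- out[[ncol(out)]][idx]
    out <- out[idx, , drop = FALSE]
    out[[rank]] <- sprintf("%s-%s%02d", parentName, labs[[rank]],
                           rep(seq_len(cpn), times = nparent))
    rownames(out) <- NULL
  }
  out[, c("genus", "family", "order", "class", "phylum")]
}

.rdirichlet <- function(n, conc) {
  g <- rgamma(n, shape = conc)
  if (sum(g) <= 0) g <- rep(1, n)
  g / sum(g)
}

# Project a 64-long 3-mer weight vector onto the set of distributions
# realizable as the stationary 3-mer law of the order-2 Markov chain it
# induces: p*(abc) = pi(ab) T(c|ab), with pi the stationary 2-mer law.
# Without this projection an arbitrary Dirichlet draw is not marginally
# consistent and the emitted genome's composition would only loosely track
# its nominal profile.
.consistentProfile <- function(p) {
  Tm <- matrix(p, 4, 16)            # column = context (a,b), row = next base
  cs <- colSums(Tm)
  Tm[, cs == 0] <- 0.25             # uniform fallback, as in the sampler
  Tm <- sweep(Tm, 2, colSums(Tm), "/")
  # 2-mer chain: state (a,b) -> (b,c)
  P <- matrix(0, 16, 16)
  for (a in 0:3) for (b in 0:3) for (cc in 0:3)
    P[4 * a + b + 1, 4 * b + cc + 1] <- Tm[cc + 1, 4 * a + b + 1]
  pi2 <- rep(1 / 16, 16)
  for (i in 1:300) {
    nxt <- as.vector(pi2 %*% P)
    if (max(abs(nxt - pi2)) < 1e-13) { pi2 <- nxt; break }
    pi2 <- nxt
  }
  out <- as.vector(Tm * rep(pi2, each = 4))  # index 16a+4b+c, c fastest
  out / sum(out)
}

#' Draw clade composition profiles for a taxonomy
#'
#' One 64-long 3-mer probability vector per clade at every rank; children
#' mix their parent's profile with fresh Dirichlet noise. Deterministic
#' given `cfg$seed`.
#'
#' @param taxonomy data.frame from [generateTaxonomy()].
#' @param cfg a [syntheticConfig()].
#' @return named list mapping every clade name (all ranks) to a profile;
#'   host genomes are generated from their genus profile.
#' @export
generateCladeProfiles <- function(taxonomy, cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  .withSeed(stageSeed(cfg$seed, "profiles"), {
    profiles <- list()
    for (ph in unique(taxonomy$phylum))
      profiles[[ph]] <- .rdirichlet(64, cfg$profile_concentration)
    w <- cfg$rank_inheritance
    parentOf <- c(class = "phylum", order = "class", family = "order",
                  genus = "family")
    for (rank in names(parentOf)) {
      tab <- unique(taxonomy[, c(rank, parentOf[[rank]])])
      for (i in seq_len(nrow(tab))) {
        child <- tab[[rank]][i]
        parent <- profiles[[tab[[parentOf[[rank]]]][i]]]
        profiles[[child]] <- w * parent +
          (1 - w) * .rdirichlet(64, cfg$profile_concentration)
      }
    }
    # every stored profile is chain-consistent, so a genome generated from
    # it reproduces the profile as its (overlapping) 3-mer composition
    lapply(profiles, .consistentProfile)
  })
}

.lineageAsList <- function(lineage) {
  if (is.data.frame(lineage)) lineage <- as.list(lineage[1, , drop = FALSE])
  lin <- lapply(RANKS, function(r) as.character(lineage[[r]]))
  names(lin) <- RANKS
  if (any(vapply(lin, function(z) length(z) != 1 || is.na(z) || !nzchar(z),
                 logical(1))))
    .phnStop("data", "lineage must have non-empty genus..phylum fields")
  lin
}

#' Generate one host genome from its clade profile
#'
#' Samples `cfg$host_length` bases from the order-2 Markov chain induced by
#' the host genus's 3-mer profile. Uses the current RNG state; seed via
#' [simulateDataset()] or `set.seed()` for reproducibility.
#'
#' @param lineage one-row data.frame or named list with the five ranks.
#' @param profiles list from [generateCladeProfiles()].
#' @param cfg a [syntheticConfig()].
#' @param id genome id.
#' @return a genome record: list with `id`, `sequence`, `role = "host"`,
#'   `lineage`.
#' @export
generateHostGenome <- function(lineage, profiles, cfg, id) {
  lin <- .lineageAsList(lineage)
  prof <- profiles[[lin$genus]]
  if (is.null(prof))
    .phnStop("data", sprintf("no profile for genus '%s'", lin$genus))
  list(id = as.character(id),
       sequence = cpp_markov_sample(prof, as.integer(cfg$host_length)),
       role = "host", lineage = lin, true_host_id = NA_character_)
}

#' Generate one phage genome that mimics its host's composition
#'
#' The generating 3-mer distribution is
#' `mimicry_strength * host-genus profile + (1 - mimicry_strength) * uniform`,
#' so `mimicry_strength = 0` gives a uniform background genome and
#' `mimicry_strength = 1` reproduces the host clade's composition.
#'
#' @param host a host genome record from [generateHostGenome()].
#' @param profiles list from [generateCladeProfiles()].
#' @param cfg a [syntheticConfig()].
#' @param id genome id.
#' @return a genome record carrying `true_host_id` and the host's lineage.
#' @export
generatePhageGenome <- function(host, profiles, cfg, id) {
  lin <- .lineageAsList(host$lineage)
  prof <- profiles[[lin$genus]]
  if (is.null(prof))
    .phnStop("data", sprintf("no profile for genus '%s'", lin$genus))
  m <- cfg$mimicry_strength
  mix <- .consistentProfile(m * prof + (1 - m) * rep(1 / 64, 64))
  list(id = as.character(id),
       sequence = cpp_markov_sample(mix, as.integer(cfg$phage_length)),
       role = "phage", lineage = lin, true_host_id = host$id)
}

# Normalize genome records / meta data.frames to (id, phylum, true_host_id).
.pairTable <- function(x) {
  if (is.data.frame(x)) {
    n <- nrow(x)
    col <- function(nm) if (!is.null(x[[nm]])) as.character(x[[nm]])
                        else rep(NA_character_, n)
    data.frame(id = as.character(x$id), phylum = col("phylum"),
               true_host_id = col("true_host_id"), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(x, function(r) data.frame(
      id = r$id, phylum = r$lineage$phylum,
      true_host_id = if (is.null(r$true_host_id) || is.na(r$true_host_id))
        NA_character_ else r$true_host_id,
      stringsAsFactors = FALSE)))
  }
}

#' Build a labeled pair dataset with phylum-exclusion negatives
#'
#' One positive pair per phage (its true host); `negatives_per_positive`
#' negatives per phage drawn without replacement, uniformly among hosts
#' whose phylum differs from the true host's phylum. Deterministic given
#' `seed`.
#'
#' @param phages list of phage records or a data.frame with `id`,
#'   `true_host_id` (phylum is looked up from `hosts`).
#' @param hosts list of host records or a data.frame with `id`, `phylum`.
#' @param negatives_per_positive negatives sampled per phage (default 1).
#' @param seed RNG seed.
#' @return data.frame with columns `phage_id`, `host_id`, `label`
#'   (1 = match, 0 = non-match), without duplicate pairs.
#' @export
buildPairDataset <- function(phages, hosts, negatives_per_positive = 1L,
                             seed = 1L) {
  .assertCount(negatives_per_positive, "negatives_per_positive")
  ht <- .pairTable(hosts)
  pt <- .pairTable(phages)
  if (anyNA(pt$true_host_id) || !all(pt$true_host_id %in% ht$id))
    .phnStop("data", "every phage's true host must be among the hosts")
  if (length(unique(ht$phylum)) < 2)
    .phnStop("data", paste("phylum-exclusion negative sampling is infeasible:",
                           "all hosts belong to a single phylum"))
  truePhylum <- ht$phylum[match(pt$true_host_id, ht$id)]
  .withSeed(seed, {
    neg <- vector("list", nrow(pt))
    for (i in seq_len(nrow(pt))) {
      cand <- ht$id[ht$phylum != truePhylum[i]]
      if (length(cand) < negatives_per_positive)
        .phnStop("data", sprintf(
          "phage '%s': only %d hosts outside phylum '%s' (need %d)",
          pt$id[i], length(cand), truePhylum[i], negatives_per_positive))
      neg[[i]] <- sort(cand)[sample.int(length(cand), negatives_per_positive)]
    }
    rbind(
      data.frame(phage_id = pt$id, host_id = pt$true_host_id, label = 1L,
                 stringsAsFactors = FALSE),
      data.frame(phage_id = rep(pt$id, each = negatives_per_positive),
                 host_id = unlist(neg), label = 0L, stringsAsFactors = FALSE))
  })
}

#' Simulate a complete phage-host dataset
#'
#' Runs the full generator: taxonomy, clade profiles, host genomes, phage
#' genomes, and the labeled pair set. A pure function of `cfg` (all
#' randomness derives from `cfg$seed`).
#'
#' @param cfg a [syntheticConfig()].
#' @param negatives_per_positive negatives per phage (default 1).
#' @return a [PhageHostDataSet-class].
#' @export
#' @examples
#' ds <- simulateDataset(syntheticConfig(n_phyla = 2, hosts_per_genus = 1,
#'   phages_per_host = 1, host_length = 3000, phage_length = 3000))
#' ds
simulateDataset <- function(cfg, negatives_per_positive = 1L) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  taxonomy <- generateTaxonomy(cfg)
  profiles <- generateCladeProfiles(taxonomy, cfg)
  recs <- .withSeed(stageSeed(cfg$seed, "genomes"), {
    hosts <- list()
    for (g in seq_len(nrow(taxonomy)))
      for (i in seq_len(cfg$hosts_per_genus)) {
        id <- sprintf("host_%03d_%02d", g, i)
        hosts[[id]] <- generateHostGenome(taxonomy[g, ], profiles, cfg, id)
      }
    phages <- list()
    for (h in hosts)
      for (j in seq_len(cfg$phages_per_host)) {
        id <- sprintf("phage_%s_%02d", sub("^host_", "", h$id), j)
        phages[[id]] <- generatePhageGenome(h, profiles, cfg, id)
      }
    list(hosts = hosts, phages = phages)
  })
  pairs <- buildPairDataset(recs$phages, recs$hosts,
                            negatives_per_positive = negatives_per_positive,
                            seed = stageSeed(cfg$seed, "pairs"))
  all <- c(recs$hosts, recs$phages)
  meta <- do.call(rbind, lapply(all, function(r) data.frame(
    id = r$id, role = r$role,
    genus = r$lineage$genus, family = r$lineage$family,
    order = r$lineage$order, class = r$lineage$class,
    phylum = r$lineage$phylum, true_host_id = r$true_host_id,
    stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  seqs <- vapply(all, `[[`, character(1), "sequence")
  names(seqs) <- vapply(all, `[[`, character(1), "id")
  PhageHostDataSet(seqs, meta, pairs,
                   profiles = profiles[unique(taxonomy$genus)],
                   config = unclass(cfg))
}

#' Overlapping 3-mer frequency vector of a sequence
#'
#' @param sequence character scalar.
#' @return numeric vector of length 64 summing to 1 (lexicographic order),
#'   UNK windows excluded.
#' @export
kmerFrequencies <- function(sequence) {
  ids <- .tokenIds(as.character(sequence), 3L)
  cnt <- tabulate(ids[ids <= 64L], nbins = 64L)
  if (sum(cnt) == 0) .phnStop("data", "sequence has no ACGT 3-mers")
  stats::setNames(cnt / sum(cnt), buildVocabulary(3L)[1:64])
}

#' Nearest-composition-host baseline
#'
#' Alignment-free baseline: each phage is assigned the host whose
#' overlapping 3-mer frequency vector has the highest cosine similarity to
#' the phage's. Serves as an independent check that the planted
#' compositional signal in simulated data is recoverable at all.
#'
#' @param phageSeqs,hostSeqs named character vectors (or `DNAStringSet`s).
#' @return named character vector: predicted host id per phage.
#' @export
nearestCompositionHost <- function(phageSeqs, hostSeqs) {
  hostIds <- names(hostSeqs)
  if (is.null(hostIds)) .phnStop("contract", "hostSeqs must be named")
  Hm <- vapply(unname(as.character(hostSeqs)), kmerFrequencies, numeric(64),
               USE.NAMES = FALSE)
  Hm <- sweep(Hm, 2, sqrt(colSums(Hm^2)), "/")
  ord <- order(hostIds)  # lexicographic tie-break
  out <- vapply(unname(as.character(phageSeqs)), function(s) {
    f <- kmerFrequencies(s)
    f <- f / sqrt(sum(f^2))
    sims <- stats::setNames(as.vector(crossprod(Hm, f)), hostIds)[ord]
    names(sims)[which.max(sims)]
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(phageSeqs)
  out
}
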