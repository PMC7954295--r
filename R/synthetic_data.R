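# Synthetic phage populations with ground truth. The generator emulates
# the statistical structure the analysis assumes: cluster-structured
# pham sharing, orphams, cross-cluster shared (HGT-like) genes,
# controllable per-gene GC content, and synonymous codon scrambling
# that preserves every protein exactly while erasing nucleotide-level
# identity between clusters.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG
# state afterwards so generator streams never perturb each other.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# ---- codon machinery -------------------------------------------------------

codon_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      code <- Biostrings::getGeneticCode("11")
      by_aa <- split(names(code), unname(code))
      stops <- by_aa[["*"]]
      by_aa[["*"]] <- NULL
      gcc <- vapply(names(code), function(c) nchar(gsub("[^GC]", "", c)), integer(1))
      cache <<- list(by_aa = by_aa, stops = stops, gcc = gcc)
    }
    cache
  }
})

# Expected GC fraction of a coding sequence when each amino acid's
# synonymous codons are weighted w ~ exp(beta * gc_count(codon)).
expected_gc_fraction <- function(beta, comp) {
  ct <- codon_tables()
  total <- 0
  for (aa in names(comp)) {
    cs <- ct$by_aa[[aa]]
    g <- ct$gcc[cs]
    w <- exp(beta * g)
    total <- total + comp[[aa]] * sum(w * g) / sum(w)
  }
  total / (3 * sum(unlist(comp)))
}

# Solve the codon-bias tilt beta so the expected GC matches the target.
# Returns beta plus the achievable range; warns and clamps when the
# target lies outside what the protein's composition permits.
solve_codon_beta <- function(protein, gc_target) {
  ct <- codon_tables()
  aa <- strsplit(protein, "")[[1]]
  comp <- as.list(table(aa))
  lo <- expected_gc_fraction(-50, comp)
  hi <- expected_gc_fraction(50, comp)
  target <- gc_target / 100
  if (target <= lo || target >= hi) {
    warning(sprintf(
      "GC target %.1f%% unreachable for this protein; achievable range %.1f%%-%.1f%%",
      gc_target, 100 * lo, 100 * hi), call. = FALSE)
    return(list(beta = if (target <= lo) -50 else 50, range = c(lo, hi) * 100))
  }
  beta <- stats::uniroot(function(b) expected_gc_fraction(b, comp) - target,
                         c(-50, 50), tol = 1e-8)$root
  list(beta = beta, range = c(lo, hi) * 100)
}

# Deterministic-count codon allocation: for every amino-acid type,
# codon counts follow the tilted weights by largest-remainder rounding,
# then the codons are permuted randomly over that amino acid's
# positions. Keeps realized GC tightly at the expectation while still
# varying sequence with the RNG stream.
allocate_codons <- function(aa_vec, beta) {
  ct <- codon_tables()
  out <- character(length(aa_vec))
  for (aa in unique(aa_vec)) {
    idx <- which(aa_vec == aa)
    cs <- ct$by_aa[[aa]]
    w <- exp(beta * ct$gcc[cs])
    w <- w / sum(w)
    n <- length(idx)
    counts <- floor(n * w)
    short <- n - sum(counts)
    if (short > 0) {
      frac <- n * w - counts
      counts[order(-frac)[seq_len(short)]] <- counts[order(-frac)[seq_len(short)]] + 1
    }
    pool <- rep(cs, counts)
    out[idx] <- if (n == 1L) pool else sample(pool)
  }
  out
}

# Sample amino acids with composition biased toward GC-rich codons
# (weights exp(gamma * mean codon GC count)), mirroring the Ala/Gly/
# Pro/Arg-rich proteomes of high-GC actinobacteria and their phages.
# Without the bias, GC targets much above ~63% are unreachable for a
# uniformly random protein.
sample_aa <- function(n, gamma) {
  ct <- codon_tables()
  mean_gcc <- vapply(AA_LETTERS, function(a) mean(ct$gcc[ct$by_aa[[a]]]),
                     numeric(1))
  sample(AA_LETTERS, n, replace = TRUE, prob = exp(gamma * mean_gcc))
}

resample_synonymous <- function(codons, aa_vec, rate, beta) {
  if (rate <= 0) return(codons)
  ct <- codon_tables()
  hit <- which(stats::runif(length(codons)) < rate)
  for (i in hit) {
    cs <- ct$by_aa[[aa_vec[i]]]
    w <- exp(beta * ct$gcc[cs])
    codons[i] <- sample(cs, 1, prob = w)
  }
  codons
}

#' Encode a protein as nucleotides with GC-biased synonymous codons
#'
#' Chooses synonymous codons (genetic code table 11) with a
#' composition-aware bias solved so the realized GC content sits at
#' `gc_target` where the protein's composition permits (otherwise the
#' closest achievable value, with a warning giving the achievable
#' range). Translating the output always reproduces the input protein
#' exactly; different seeds give different nucleotide sequences.
#'
#' @param protein Non-empty amino-acid string.
#' @param gc_target Target GC percent.
#' @param scramble_seed Integer seed for the codon permutation.
#' @return Nucleotide string of length `3 * nchar(protein)` (no stop
#'   codon).
#' @export
codon_scramble <- function(protein, gc_target, scramble_seed) {
  protein <- check_protein(protein)
  if (nchar(protein) == 0L) stop2("empty protein")
  sol <- solve_codon_beta(protein, gc_target)
  aa_vec <- strsplit(protein, "")[[1]]
  with_seed(scramble_seed,
            paste(allocate_codons(aa_vec, sol$beta), collapse = ""))
}

# ---- simulation parameters -------------------------------------------------

#' Parameters for the synthetic phage-population generator
#'
#' Defaults describe a small actinobacteriophage-like population: three
#' clusters of small genomes (roughly 15-25 kb once realized), each
#' genome carrying 20-35 genes drawn from a shared pham universe with a
#' cluster core, a few orphams per genome, modest within-pham
#' amino-acid divergence, and complete synonymous scrambling between
#' clusters so that proteins are conserved while nucleotide identity is
#' not.
#'
#' @param seed Master integer seed; every stream is derived from it.
#' @param n_clusters Number of phage clusters.
#' @param phages_per_cluster Integer vector of cluster sizes (length
#'   `n_clusters`).
#' @param genes_per_genome Length-2 integer range of distinct gene
#'   counts per genome.
#' @param pham_universe_size Number of phams available to the designs.
#' @param core_fraction Fraction of a genome's genes that belong to its
#'   cluster core (shared by all cluster members).
#' @param cross_cluster_share Fraction of the core shared across all
#'   clusters.
#' @param orphams_per_genome Unique single-phage phams per genome.
#' @param within_pham_aa_divergence Per-site amino-acid substitution
#'   probability between a pham member and the pham reference.
#' @param synonymous_scramble_rate Probability that a codon is re-drawn
#'   synonymously between clusters (1 = independent codon choices).
#' @param within_cluster_codon_noise Per-codon synonymous resampling
#'   probability between members of the same cluster.
#' @param gc_target Population GC percent target.
#' @param gene_gc_sd Standard deviation of per-pham GC targets around
#'   `gc_target` (percentage points).
#' @param aa_gc_bias Composition bias of reference proteins toward
#'   amino acids with GC-rich codons (0 = uniform; default 1).
#' @param protein_len Length-2 range of reference protein lengths (aa).
#' @param spacer_len Length-2 range of intergenic spacer lengths (bp).
#' @param reverse_genes_per_genome Reverse-strand genes per genome.
#' @param hgt_implants List of implants, each
#'   `list(slot =, gc_offset =, n_extra_hosts =)`, applied to the focal
#'   phage (see [simulate_population()]).
#' @param focal_phage Name of the phage receiving the implants; default
#'   the first phage generated.
#' @param profile_design Optional explicit design overriding the
#'   random profile layout (used by the scenario presets).
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L,
                              n_clusters = 3L,
                              phages_per_cluster = c(4L, 3L, 2L),
                              genes_per_genome = c(20L, 35L),
                              pham_universe_size = 200L,
                              core_fraction = 0.6,
                              cross_cluster_share = 0.1,
                              orphams_per_genome = 2L,
                              within_pham_aa_divergence = 0.05,
                              synonymous_scramble_rate = 1,
                              within_cluster_codon_noise = 0.02,
                              gc_target = 64.3,
                              gene_gc_sd = 1.5,
                              aa_gc_bias = 1,
                              protein_len = c(100L, 250L),
                              spacer_len = c(10L, 50L),
                              reverse_genes_per_genome = 1L,
                              hgt_implants = list(),
                              focal_phage = NULL,
                              profile_design = NULL) {
  p <- as.list(environment())
  probs <- c(core_fraction, cross_cluster_share, within_pham_aa_divergence,
             synonymous_scramble_rate, within_cluster_codon_noise)
  if (any(probs < 0) || any(probs > 1)) stop2("probabilities must lie in [0, 1]")
  if (length(phages_per_cluster) != n_clusters)
    stop2("phages_per_cluster must have length n_clusters")
  if (genes_per_genome[1] < orphams_per_genome + 1L)
    stop2("genes_per_genome must exceed orphams_per_genome")
  class(p) <- "simulation_params"
  p
}

host_pool <- function() c(
  "Arthrobacter globiformis B-2979",
  "Arthrobacter sp. ATCC 21022",
  "Microbacterium foliorum NRRL B-24224",
  "Gordonia malaquae BEN700",
  "Mycobacterium smegmatis mc2 155",
  "Gordonia rubripertincta NRRL B-16540",
  "Microbacterium paraoxydans NWU1",
  "Gordonia terrae 3612")

# Random cluster/profile layout for generic parameters. Every cluster
# gets a core (a slice of which is shared across all clusters), a
# private accessory pool, and per-genome orphams.
design_profiles_generic <- function(params) {
  with_seed(derive_seed(params$seed, 1L), {
    n_core <- round(params$core_fraction *
                      (params$genes_per_genome[1] - params$orphams_per_genome))
    n_shared <- round(params$cross_cluster_share * n_core)
    universe <- sprintf("U%04d", seq_len(params$pham_universe_size))
    need <- n_shared + params$n_clusters * (n_core - n_shared + 2 * params$genes_per_genome[2])
    if (need > length(universe))
      stop2("infeasible parameters: design needs %d phams but universe has %d",
            need, length(universe))
    pool <- universe
    take <- function(n) {
      if (n == 0L) return(character(0))
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    shared_core <- take(n_shared)
    phages <- list(); genes <- list()
    idx <- 0L
    for (c in seq_len(params$n_clusters)) {
      core <- c(shared_core, take(n_core - n_shared))
      accessory <- take(2 * params$genes_per_genome[2])
      for (k in seq_len(params$phages_per_cluster[c])) {
        idx <- idx + 1L
        name <- sprintf("SimPhage%02d", idx)
        n_genes <- sample(params$genes_per_genome[1]:params$genes_per_genome[2], 1)
        n_acc <- max(0L, n_genes - length(core) - params$orphams_per_genome)
        orph <- sprintf("ORPH_%s_%d", name, seq_len(params$orphams_per_genome))
        slots <- c(core, sample(accessory, n_acc), orph)
        genes[[name]] <- sample(slots)  # shuffle gene order along the genome
        phages[[name]] <- data.frame(
          phage = name, cluster = sprintf("SC%d", c),
          host = host_pool()[(c - 1L) %% length(host_pool()) + 1L],
          stringsAsFactors = FALSE)
      }
    }
    list(phages = do.call(rbind, phages), gene_phams = genes,
         reverse_slots = NULL)
  })
}

#' Scenario preset: a putative singleton bridging two small clusters
#'
#' Six small phages emulating the reclustering study design: a
#' three-phage cluster FE (Corgi, Idaho, Noely), a two-phage cluster FI
#' (Whytu, Yavru), and the focal phage BlueFeather, originally a
#' singleton. Pham sharing is laid out so that the focal phage shares
#' well over 35% of gene content with FE members and over 55% with FI
#' members while every pairwise GCS in the group exceeds 35%, and the
#' between-cluster synonymous scramble rate of 1 removes nucleotide
#' identity between clusters entirely. The focal genome carries 25
#' genes, 6 of them orphams, 1 on the reverse strand, with GC-offset
#' and multi-host implants at the slots where single-gene evidence is
#' examined.
#'
#' @param seed Master seed.
#' @param outgroup_clusters Additional unrelated clusters (no shared
#'   phams with the six focal phages), for phylogeny tests; default 0.
#' @param phages_per_outgroup Phages per outgroup cluster.
#' @return A `simulation_params` with an explicit `profile_design`.
#' @export
bluefeather_scenario_params <- function(seed = 1L, outgroup_clusters = 0L,
                                        phages_per_outgroup = 3L) {
  s_all <- sprintf("SA%02d", 1:9)    # expanded-cluster core, all six phages
  s_fibf <- sprintf("SB%02d", 1:5)   # focal + FI only
  s_febf <- sprintf("SC%02d", 1:2)   # focal + FE only
  s_fe <- sprintf("SD%02d", 1:12)    # FE private core
  s_fi <- sprintf("SE%02d", 1:9)     # FI private core
  orph <- function(p, n) sprintf("ORPH_%s_%d", p, seq_len(n))

  fe_genes <- function(p) c(s_all, s_febf, s_fe, orph(p, 2))          # 25
  fi_genes <- function(p) c(s_all, s_fibf, s_fi, orph(p, 2))          # 25
  # focal gene layout (25 genes, 23 distinct phams):
  #   1-9   expanded-cluster core           10-14 shared with FI only
  #   15-16 shared with FE only (15 also spans extra hosts)
  #   17-18, 20-23  the six orphams
  #   19    reverse-strand gene found otherwise only in carrier phages
  #   24-25 paralogs of core phams (24 carries the high-GC implant)
  # shared counts give GCS 58.4 vs FI members and 45.9 vs FE members
  bf_orph <- orph("BlueFeather", 6)
  bf_genes <- c(s_all, s_fibf, s_febf, bf_orph[1:2], "SH01",
                bf_orph[3:6], s_all[1:2])

  phages <- data.frame(
    phage = c("BlueFeather", "Corgi", "Idaho", "Noely", "Whytu", "Yavru"),
    cluster = c("BF", "FE", "FE", "FE", "FI", "FI"),
    host = c("Arthrobacter globiformis B-2979",
             rep("Arthrobacter globiformis B-2979", 3),
             rep("Arthrobacter sp. ATCC 21022", 2)),
    stringsAsFactors = FALSE)
  genes <- list(BlueFeather = bf_genes,
                Corgi = fe_genes("Corgi"), Idaho = fe_genes("Idaho"),
                Noely = fe_genes("Noely"),
                Whytu = fi_genes("Whytu"), Yavru = fi_genes("Yavru"))

  if (outgroup_clusters > 0L) {
    for (c in seq_len(outgroup_clusters)) {
      core <- sprintf("OG%d_%02d", c, 1:20)
      for (k in seq_len(phages_per_outgroup)) {
        name <- sprintf("Outgroup%d_%d", c, k)
        genes[[name]] <- c(core, orph(name, 2))
        phages <- rbind(phages, data.frame(
          phage = name, cluster = sprintf("OG%d", c),
          host = sprintf("Arthrobacter sp. OG%d", c),  # outside the carrier host pool
          stringsAsFactors = FALSE))
      }
    }
  }

  simulation_params(
    seed = seed,
    n_clusters = length(unique(phages$cluster)),
    phages_per_cluster = as.integer(table(factor(phages$cluster,
                                                 levels = unique(phages$cluster)))),
    genes_per_genome = c(25L, 27L),
    protein_len = c(150L, 260L),
    orphams_per_genome = 2L,
    within_pham_aa_divergence = 0.05,
    synonymous_scramble_rate = 1,
    within_cluster_codon_noise = 0.02,
    gc_target = 64.3,
    gene_gc_sd = 1.5,
    focal_phage = "BlueFeather",
    hgt_implants = list(
      list(slot = 15L, gc_offset = 6, n_extra_hosts = 4L),
      list(slot = 19L, gc_offset = 0, n_extra_hosts = 2L),
      list(slot = 24L, gc_offset = 5.8, n_extra_hosts = 0L)),
    profile_design = list(phages = phages, gene_phams = genes,
                          reverse_slots = list(BlueFeather = 19L)))
}

# ---- population realization ------------------------------------------------

#' Simulate an annotated phage population with ground truth
#'
#' Deterministic for a fixed seed: population-level structure (profile
#' layout, pham reference proteins, per-cluster codon choices) and each
#' phage's realization run on independent derived RNG streams, so
#' extending a population does not perturb existing genomes.
#'
#' Implants listed in `hgt_implants` modify the focal phage: a GC
#' offset shifts that gene's codon GC target, and `n_extra_hosts > 0`
#' adds that many small carrier phages (cluster `"EX"`), each on a
#' distinct novel host and carrying the implanted pham, so the pham
#' spans multiple isolation hosts exactly as horizontally transferred
#' genes do.
#'
#' @param params A `simulation_params`.
#' @return List with `genomes` (list of `annotated_genome`), `metadata`
#'   (phage/host/original_cluster data.frame; the focal phage is
#'   recorded as `"singleton"` when its design cluster holds only
#'   itself), and `truth` (class `synthetic_truth`: `pham_of` per gene,
#'   `clusters` per phage, `profiles`, `hgt_genes`, `gene_gc_target`).
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  design <- params$profile_design %||% design_profiles_generic(params)
  focal <- params$focal_phage %||% design$phages$phage[1]

  # carrier phages for multi-host implants
  implants <- params$hgt_implants
  carrier_i <- 0L
  for (imp in implants) {
    if (imp$n_extra_hosts <= 0L) next
    pham <- design$gene_phams[[focal]][imp$slot]
    used_hosts <- unique(design$phages$host)
    fresh <- setdiff(host_pool(), used_hosts)
    if (length(fresh) < imp$n_extra_hosts)
      stop2("infeasible: not enough distinct hosts for implant at slot %d", imp$slot)
    for (k in seq_len(imp$n_extra_hosts)) {
      carrier_i <- carrier_i + 1L
      name <- sprintf("Carrier%02d", carrier_i)
      design$gene_phams[[name]] <-
        c(pham, sprintf("ORPH_%s_%d", name, 1:4))
      design$phages <- rbind(design$phages, data.frame(
        phage = name, cluster = sprintf("EX%02d", carrier_i),
        host = fresh[k], stringsAsFactors = FALSE))
    }
  }

  phage_names <- design$phages$phage
  cluster_of <- stats::setNames(design$phages$cluster, phage_names)
  all_phams <- sort(unique(unlist(design$gene_phams)))
  pham_idx <- stats::setNames(seq_along(all_phams), all_phams)

  # per-pham reference proteins and GC targets (independent streams)
  refs <- lapply(all_phams, function(p) {
    with_seed(derive_seed(params$seed, 1000L + pham_idx[[p]]), {
      len <- sample(params$protein_len[1]:params$protein_len[2], 1)
      aa <- c("M", sample_aa(len - 1L, params$aa_gc_bias))
      gc <- min(85, max(25, stats::rnorm(1, params$gc_target, params$gene_gc_sd)))
      list(aa = aa, gc = gc, beta = solve_codon_beta(paste(aa, collapse = ""), gc)$beta)
    })
  })
  names(refs) <- all_phams

  # per-(pham, cluster) codon baselines: first cluster draws fresh,
  # later clusters re-draw each codon with the scramble rate
  cluster_codons <- new.env(parent = emptyenv())
  codons_for <- function(pham, cluster) {
    keyc <- paste0(pham, "\r", cluster)
    if (!is.null(cluster_codons[[keyc]])) return(cluster_codons[[keyc]])
    ref <- refs[[pham]]
    clusters <- unique(cluster_of[vapply(design$gene_phams, function(g)
      pham %in% g, logical(1))])
    m <- match(cluster, clusters)
    base <- with_seed(derive_seed(params$seed, 2000L + pham_idx[[pham]]),
                      allocate_codons(ref$aa, ref$beta))
    cod <- if (m == 1L) base else
      with_seed(derive_seed(derive_seed(params$seed, 2000L + pham_idx[[pham]]), m),
                resample_synonymous(base, ref$aa,
                                    params$synonymous_scramble_rate, ref$beta))
    cluster_codons[[keyc]] <- cod
    cod
  }

  implant_at <- function(phage, slot) {
    if (phage != focal) return(NULL)
    for (imp in implants) if (imp$slot == slot) return(imp)
    NULL
  }

  genomes <- vector("list", length(phage_names))
  truth_pham <- character(0); truth_gc <- numeric(0)
  hgt_rows <- list()

  for (pi in seq_along(phage_names)) {
    phage <- phage_names[pi]
    slots <- design$gene_phams[[phage]]
    genome <- with_seed(derive_seed(params$seed, 10L + pi), {
      n <- length(slots)
      rev_slot <- design$reverse_slots[[phage]] %||%
        if (params$reverse_genes_per_genome > 0L && n > 1L)
          sample(2:n, min(params$reverse_genes_per_genome, n - 1L)) else integer(0)
      gene_nt <- character(n); gene_aa <- character(n); gc_t <- numeric(n)
      ct <- codon_tables()
      for (s in seq_len(n)) {
        pham <- slots[s]
        ref <- refs[[pham]]
        aa <- ref$aa
        if (params$within_pham_aa_divergence > 0) {
          mut <- which(stats::runif(length(aa) - 1L) < params$within_pham_aa_divergence) + 1L
          for (i in mut) aa[i] <- sample(setdiff(AA_LETTERS, aa[i]), 1)
        }
        imp <- implant_at(phage, s)
        if (!is.null(imp) && imp$gc_offset != 0) {
          gc <- ref$gc + imp$gc_offset
          beta <- solve_codon_beta(paste(aa, collapse = ""), gc)$beta
          cod <- allocate_codons(aa, beta)
        } else {
          gc <- ref$gc
          beta <- ref$beta
          cod <- codons_for(pham, cluster_of[[phage]])
          changed <- which(aa != ref$aa)
          for (i in changed) {
            cs <- ct$by_aa[[aa[i]]]
            cod[i] <- sample(cs, 1, prob = exp(beta * ct$gcc[cs]))
          }
          cod <- resample_synonymous(cod, aa, params$within_cluster_codon_noise, beta)
        }
        stopc <- sample(ct$stops, 1, prob = exp(beta * ct$gcc[ct$stops]))
        gene_nt[s] <- paste(c(cod, stopc), collapse = "")
        gene_aa[s] <- paste(aa, collapse = "")
        gc_t[s] <- gc
      }
      spacers <- vapply(seq_len(n + 1L), function(i) {
        len <- sample(params$spacer_len[1]:params$spacer_len[2], 1)
        paste(sample(DNA_BASES, len, replace = TRUE,
                     prob = c((100 - params$gc_target) / 2, params$gc_target / 2,
                              params$gc_target / 2, (100 - params$gc_target) / 2)),
              collapse = "")
      }, character(1))
      pos <- nchar(spacers[1])
      starts <- integer(n); ends <- integer(n); pieces <- character(2 * n + 1L)
      pieces[1] <- spacers[1]
      for (s in seq_len(n)) {
        starts[s] <- pos + 1L
        ends[s] <- pos + nchar(gene_nt[s])
        pieces[2 * s] <- if (s %in% rev_slot) revcomp(gene_nt[s]) else gene_nt[s]
        pieces[2 * s + 1L] <- spacers[s + 1L]
        pos <- ends[s] + nchar(spacers[s + 1L])
      }
      genes <- data.frame(
        gene_number = seq_len(n), start = starts, end = ends,
        strand = ifelse(seq_len(n) %in% rev_slot, "-", "+"),
        nucleotide_seq = gene_nt, protein_seq = gene_aa,
        function_label = ifelse(startsWith(slots, "ORPH"), "unknown",
                                paste("conserved protein", slots)),
        stringsAsFactors = FALSE)
      list(genome = annotated_genome(
             phage, paste(pieces, collapse = ""), genes,
             host = design$phages$host[pi],
             original_cluster = cluster_of[[phage]]),
           gc_t = gc_t)
    })
    genomes[[pi]] <- genome$genome
    ids <- gene_id(phage, seq_along(slots))
    truth_pham[ids] <- slots
    truth_gc[ids] <- genome$gc_t
  }
  names(genomes) <- phage_names

  for (imp in implants) {
    hgt_rows[[length(hgt_rows) + 1L]] <- data.frame(
      phage = focal, gene_number = imp$slot,
      pham = design$gene_phams[[focal]][imp$slot],
      gc_offset = imp$gc_offset, n_extra_hosts = imp$n_extra_hosts,
      stringsAsFactors = FALSE)
  }

  metadata <- data.frame(
    phage_name = phage_names,
    host = design$phages$host,
    original_cluster = ifelse(phage_names %in% names(cluster_of)[
      cluster_of %in% names(which(table(cluster_of) == 1))],
      "singleton", design$phages$cluster),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    pham_of = truth_pham,
    clusters = cluster_of,
    profiles = lapply(design$gene_phams, function(g) sort(unique(g))),
    hgt_genes = if (length(hgt_rows)) do.call(rbind, hgt_rows) else
      data.frame(phage = character(), gene_number = integer(),
                 pham = character(), gc_offset = numeric(),
                 n_extra_hosts = integer()),
    gene_gc_target = truth_gc,
    params = params), class = "synthetic_truth")

  list(genomes = genomes, metadata = metadata, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes in %d phages; %d implanted HGT genes\n",
              length(x$pham_of), length(x$clusters), nrow(x$hgt_genes)))
  invisible(x)
}

#' Write a synthetic population and its ground truth to disk
#'
#' Emits `genomes.fasta`, `genes.tsv` and `metadata.tsv` in the
#' package's input dialects (loadable by the io readers), plus
#' `truth_phams.tsv` (pham-table dialect), `truth_clusters.tsv` and
#' `truth_hgt.tsv`.
#'
#' @param population Result of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- population$genomes
  write_genome_fasta(vapply(g, function(x) x$sequence, character(1)),
                     file.path(dir, "genomes.fasta"))
  genes <- do.call(rbind, lapply(g, genes_tsv_from_genome))
  write_genes_tsv(genes, file.path(dir, "genes.tsv"))
  write_metadata_table(population$metadata, file.path(dir, "metadata.tsv"))

  tr <- population$truth
  ids <- names(tr$pham_of)
  phage <- sub("\\|.*$", "", ids)
  counts <- table(tr$pham_of, phage)
  orpham <- rowSums(counts > 0) == 1L
  utils::write.table(
    data.frame(pham_id = unname(tr$pham_of), phage_name = phage,
               gene_number = sub("^.*\\|", "", ids),
               orpham = as.integer(orpham[tr$pham_of]),
               stringsAsFactors = FALSE),
    file.path(dir, "truth_phams.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(phage_name = names(tr$clusters), cluster = unname(tr$clusters)),
    file.path(dir, "truth_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(tr$hgt_genes, file.path(dir, "truth_hgt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# ---- synthetic reference-like record ---------------------------------------

#' Synthetic stand-in for a small annotated phage record
#'
#' Generates, entirely in code, an annotated genome whose headline
#' statistics emulate the deposited BlueFeather record: exactly
#' 16,302 bp; 25 genes of which one (gene 19) lies on the reverse
#' strand and several have no known function; per-gene GC targets
#' pinned to span 59.3-70.3% (genes 15 and 24 high at 70.3 and 70.1)
#' around a 64.3% genome target. This object is synthetic: it shares
#' summary statistics with the real record by construction, not
#' sequence, and exists so the GenBank round trip and the per-gene GC
#' machinery can be exercised without the deposited accession.
#'
#' @param seed Integer seed.
#' @return An `annotated_genome` named `"BlueFeatherSyn"`.
#' @export
simulate_bluefeather_like_record <- function(seed = 1L) {
  with_seed(derive_seed(seed, 99L), {
    n <- 25L
    total_aa <- 5100L  # 25 stops + 3*5100 coding + 927 spacer = 16302
    lens <- rep(total_aa %/% n, n)
    lens[seq_len(total_aa %% n)] <- lens[seq_len(total_aa %% n)] + 1L
    for (i in 1:200) {  # redistribute length, preserving the total
      ab <- sample(n, 2)
      d <- sample(-25:25, 1)
      if (lens[ab[1]] + d >= 120 && lens[ab[2]] - d >= 120) {
        lens[ab[1]] <- lens[ab[1]] + d
        lens[ab[2]] <- lens[ab[2]] - d
      }
    }
    sp <- rep(35L, n + 1L)
    need <- 16302L - (3L * total_aa + 3L * n) - sum(sp)
    sp[seq_len(abs(need))] <- sp[seq_len(abs(need))] + sign(need)

    gc_t <- pmin(69.4, pmax(59.9, stats::rnorm(n, 64.3, 1.8)))
    gc_t[15] <- 70.3; gc_t[24] <- 70.1; gc_t[7] <- 59.3
    free <- setdiff(seq_len(n), c(7L, 15L, 24L))
    # nudge the free genes so the coding-weighted mean sits at 64.3
    target_sum <- 64.3 * sum(lens)
    gc_t[free] <- pmin(69.4, pmax(59.9, gc_t[free] +
      (target_sum - sum(gc_t * lens)) / sum(lens[free])))

    known <- c("terminase", "portal protein", "head-to-tail adaptor",
               "major capsid protein", "major tail protein", "tail terminator",
               "tape measure protein", "minor tail protein", "lysin A", "holin",
               "DNA primase", "DNA polymerase", "helicase", "endonuclease",
               "RecB-like exonuclease", "DNA binding protein",
               "RNA polymerase sigma factor", "membrane protein")
    labels <- rep("unknown", n)
    labels[sort(sample(n, length(known)))] <- known

    ct <- codon_tables()
    gene_nt <- character(n); gene_aa <- character(n)
    for (s in seq_len(n)) {
      aa <- c("M", sample_aa(lens[s] - 1L, 1))
      beta <- solve_codon_beta(paste(aa, collapse = ""), gc_t[s])$beta
      stopc <- sample(ct$stops, 1, prob = exp(beta * ct$gcc[ct$stops]))
      gene_nt[s] <- paste(c(allocate_codons(aa, beta), stopc), collapse = "")
      gene_aa[s] <- paste(aa, collapse = "")
    }
    spacers <- vapply(sp, function(len)
      paste(sample(DNA_BASES, len, replace = TRUE,
                   prob = c(17.85, 32.15, 32.15, 17.85)), collapse = ""),
      character(1))

    pos <- nchar(spacers[1])
    starts <- integer(n); ends <- integer(n); pieces <- character(2L * n + 1L)
    pieces[1] <- spacers[1]
    for (s in seq_len(n)) {
      starts[s] <- pos + 1L
      ends[s] <- pos + nchar(gene_nt[s])
      pieces[2 * s] <- if (s == 19L) revcomp(gene_nt[s]) else gene_nt[s]
      pieces[2 * s + 1L] <- spacers[s + 1L]
      pos <- ends[s] + nchar(spacers[s + 1L])
    }
    annotated_genome(
      "BlueFeatherSyn", paste(pieces, collapse = ""),
      data.frame(gene_number = seq_len(n), start = starts, end = ends,
                 strand = ifelse(seq_len(n) == 19L, "-", "+"),
                 nucleotide_seq = gene_nt, protein_seq = gene_aa,
                 function_label = labels, stringsAsFactors = FALSE),
      host = "Arthrobacter globiformis B-2979",
      original_cluster = "singleton")
  })
}
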