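#' Genome specification for the breeding-program simulator
#'
#' @param k Number of chromosomes.
#' @param L Chromosome length in Morgan.
#' @param n_loci Total number of bi-allelic loci, spread evenly over
#'   chromosomes with uniform random map positions.
#' @param mutation_rate Per-locus, per-gamete, per-generation allele-flip
#'   rate.
#' @return A list of class `"genome_spec"` with fields `k`, `L`, `chr`
#'   (chromosome of each locus), `pos` (map position in Morgan within its
#'   chromosome, sorted within chromosome), `mutation_rate`.
#' @export
genome_spec <- function(k = 9, L = 1.5, n_loci = 4000, mutation_rate = 1e-8) {
  stopifnot(k >= 1, L > 0, n_loci >= k, mutation_rate >= 0)
  per_chr <- diff(round(seq(0, n_loci, length.out = k + 1)))
  chr <- rep(seq_len(k), per_chr)
  pos <- unlist(lapply(per_chr, function(nc) sort(stats::runif(nc, 0, L))))
  structure(list(k = k, L = L, chr = as.integer(chr), pos = pos,
                 mutation_rate = mutation_rate),
            class = "genome_spec")
}

# One round of gametes: parent[i] gives the row-pair index into H.
make_gametes <- function(H, parent, genome) {
  G <- make_gametes_cpp(H, as.integer(parent), genome$chr, genome$pos, genome$L)
  mu <- genome$mutation_rate
  if (mu > 0) {
    n_flip <- stats::rbinom(1, length(G), mu)
    if (n_flip > 0) {
      at <- sample.int(length(G), n_flip)
      G[at] <- 1L - G[at]
    }
  }
  G
}

#' Historical random-mating phase
#'
#' Generates founder haplotypes carrying drift-recombination linkage
#' disequilibrium by forward simulation of a constant-size random-mating
#' population (half males, half females), starting from loci at frequency
#' 0.5 in linkage equilibrium.
#'
#' @param genome A [genome_spec()].
#' @param ne Historical population size (individuals per generation).
#' @param n_gen Number of historical generations.
#' @return A list of class `"founder_pool"`: `H` (haplotype matrix,
#'   `2 * ne` rows), `genome`, `ne`.
#' @export
simulate_historical <- function(genome, ne = 100, n_gen = 150) {
  stopifnot(inherits(genome, "genome_spec"), ne >= 2, n_gen >= 1)
  m <- length(genome$chr)
  H <- matrix(stats::rbinom(2L * ne * m, 1L, 0.5), nrow = 2L * ne, ncol = m)
  storage.mode(H) <- "integer"
  males <- seq_len(floor(ne / 2))
  females <- seq(floor(ne / 2) + 1, ne)
  for (g in seq_len(n_gen)) {
    sires <- sample(males, ne, replace = TRUE)
    dams <- sample(females, ne, replace = TRUE)
    Hp <- make_gametes(H, sires, genome)
    Hm <- make_gametes(H, dams, genome)
    H[seq(1, 2 * ne, by = 2), ] <- Hp
    H[seq(2, 2 * ne, by = 2), ] <- Hm
  }
  p <- colMeans(H)
  if (all(p %in% c(0, 1)))
    stop("simulate_historical(): all loci fixed; increase n_loci or reduce n_gen/drift")
  structure(list(H = H, genome = genome, ne = ne), class = "founder_pool")
}

#' Assign marker and QTL loci
#'
#' From the segregating loci of a founder pool, selects loci with minor
#' allele frequency above `maf_min`, draws `n_qtl` of them as QTL (equal
#' numbers per chromosome), and uses the remainder (optionally thinned to
#' `n_markers`) as genotyped markers. QTL effects are sampled from a
#' standard normal; they are rescaled at generation 0 of the breeding phase
#' so that true breeding values have unit variance.
#'
#' @param pool A [simulate_historical()] founder pool.
#' @param maf_min Minimum minor allele frequency.
#' @param n_qtl Number of QTL; must be divisible by the number of
#'   chromosomes.
#' @param n_markers Optional cap on the number of markers (random thinning).
#' @return A list of class `"locus_map"`: `marker_idx`, `qtl_idx`,
#'   `qtl_effects` (unscaled), all relative to the pool's locus columns.
#' @export
assign_loci <- function(pool, maf_min = 0.1, n_qtl, n_markers = NULL) {
  stopifnot(inherits(pool, "founder_pool"))
  k <- pool$genome$k
  if (n_qtl %% k != 0)
    stop("assign_loci(): n_qtl must be divisible by the number of chromosomes")
  p <- colMeans(pool$H)
  maf <- pmin(p, 1 - p)
  ok <- which(maf > maf_min)
  per_chr <- n_qtl / k
  qtl <- unlist(lapply(seq_len(k), function(c) {
    cand <- ok[pool$genome$chr[ok] == c]
    if (length(cand) < per_chr)
      stop(sprintf("assign_loci(): chromosome %d has only %d loci above maf_min; need %d QTL",
                   c, length(cand), per_chr))
    sample(cand, per_chr)
  }))
  markers <- setdiff(ok, qtl)
  if (!is.null(n_markers)) {
    if (length(markers) < n_markers)
      stop(sprintf("assign_loci(): only %d candidate markers above maf_min; %d requested",
                   length(markers), n_markers))
    markers <- sort(sample(markers, n_markers))
  }
  structure(list(marker_idx = sort(markers), qtl_idx = sort(qtl),
                 qtl_effects = stats::rnorm(n_qtl)),
            class = "locus_map")
}

#' Breeding-program simulation configuration
#'
#' @param n_sires,n_dams Numbers of male and female parents selected each
#'   generation.
#' @param progeny_per_dam Progeny per dam (litters half male, half female;
#'   an odd remainder is resolved by a coin flip).
#' @param n_generations Number of breeding generations after generation 0.
#' @param h2 Heritability of the simulated phenotypes.
#' @param selection `"random"` or `"gebv"` (truncation selection on GBLUP
#'   EBV computed from previously phenotyped generations; candidates are
#'   genotyped but not yet phenotyped).
#' @param g_method VanRaden method (1 or 2) for the G matrix used when
#'   `selection = "gebv"`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_sires = 10, n_dams = 48, progeny_per_dam = 10,
                       n_generations = 6, h2 = 0.4,
                       selection = c("random", "gebv"), g_method = 1) {
  selection <- match.arg(selection)
  stopifnot(n_sires >= 1, n_dams >= n_sires, progeny_per_dam >= 1,
            n_generations >= 1, h2 > 0, h2 < 1, g_method %in% c(1, 2))
  structure(list(n_sires = n_sires, n_dams = n_dams,
                 progeny_per_dam = progeny_per_dam,
                 n_generations = n_generations, h2 = h2,
                 selection = selection, g_method = g_method),
            class = "sim_config")
}

#' Forward simulation of a breeding program
#'
#' Generation 0 is bred by random mating of the founder pool; generations
#' 1..`n_generations` by mating `n_sires` males to `n_dams` females selected
#' from the previous generation (hierarchically: dams nested within sires),
#' each dam producing `progeny_per_dam` progeny. True breeding values are
#' QTL dosages times effects, centered and scaled to unit standard
#' deviation in generation 0; phenotypes add normal environmental noise
#' with variance `(1 - h2) / h2` on that scale. Under GEBV selection,
#' parents of generation `t + 1` are the top candidates of generation `t`
#' ranked on GBLUP EBV trained on generations up to `t - 1` (the candidates
#' are not yet phenotyped); the first parent draw, and any draw with no
#' phenotyped reference yet, is random.
#'
#' @param cfg A [sim_config()].
#' @param pool A [simulate_historical()] founder pool.
#' @param map A [assign_loci()] locus map on the same pool.
#' @return A list of class `"sim_dataset"`: `pedigree` (id, sire, dam,
#'   generation, sex), `markers` (dosage matrix, all individuals),
#'   `tbv`, `phen` (id, value, generation), `generation`, `genome`, `cfg`.
#' @export
simulate_breeding <- function(cfg, pool, map) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pool, "founder_pool"),
            inherits(map, "locus_map"))
  genome <- pool$genome
  keep <- sort(c(map$marker_idx, map$qtl_idx))
  sub_genome <- genome
  sub_genome$chr <- genome$chr[keep]
  sub_genome$pos <- genome$pos[keep]
  mk <- match(map$marker_idx, keep)
  qt <- match(map$qtl_idx, keep)
  Hpool <- pool$H[, keep, drop = FALSE]

  n_per_gen <- cfg$n_dams * cfg$progeny_per_dam
  if (cfg$n_sires + cfg$n_dams > n_per_gen)
    stop("simulate_breeding(): more parents demanded than candidates per generation")
  n_total <- n_per_gen * (cfg$n_generations + 1)

  ped <- data.frame(id = character(n_total), sire = NA_character_,
                    dam = NA_character_, generation = NA_integer_,
                    sex = NA_character_, stringsAsFactors = FALSE)
  dosage <- matrix(0L, n_total, length(keep))
  H <- NULL  # haplotypes of the current generation

  dos_range <- function(g) seq(g * n_per_gen + 1L, (g + 1L) * n_per_gen)

  breed_generation <- function(Hsire, sire_pairs, Hdam, dam_pairs) {
    # sire_pairs/dam_pairs: row-pair indices of selected parents in their
    # haplotype matrices; returns haplotypes + parent indices of progeny
    n_s <- length(sire_pairs); n_d <- length(dam_pairs)
    dams_of_sire <- split(seq_len(n_d), rep(seq_len(n_s), length.out = n_d))
    dam_sire <- integer(n_d)
    for (s in seq_len(n_s)) dam_sire[dams_of_sire[[s]]] <- s
    sire_of_prog <- rep(dam_sire, each = cfg$progeny_per_dam)
    dam_of_prog <- rep(seq_len(n_d), each = cfg$progeny_per_dam)
    Hp <- make_gametes(Hsire, sire_pairs[sire_of_prog], sub_genome)
    Hm <- make_gametes(Hdam, dam_pairs[dam_of_prog], sub_genome)
    n <- nrow(Hp)
    Hnew <- matrix(0L, 2L * n, ncol(Hp))
    Hnew[seq(1, 2 * n, 2), ] <- Hp
    Hnew[seq(2, 2 * n, 2), ] <- Hm
    list(H = Hnew, sire = sire_of_prog, dam = dam_of_prog)
  }

  half_sexes <- function(n_dams, ppd) {
    # exactly half male / half female per litter; odd remainder by coin flip
    unlist(lapply(seq_len(n_dams), function(d) {
      n_m <- floor(ppd / 2) + (ppd %% 2 == 1) * stats::rbinom(1, 1, 0.5)
      sample(c(rep("M", n_m), rep("F", ppd - n_m)))
    }))
  }

  # --- generation 0: broad random mating of the founder pool --------------
  # (the structured n_sires x n_dams design starts with generation 1, so
  # generation 0 inherits the historical population's relationship
  # structure rather than an immediate family structure)
  pool_males <- seq_len(floor(pool$ne / 2))
  pool_females <- seq(floor(pool$ne / 2) + 1, pool$ne)
  Hp <- make_gametes(Hpool, sample(pool_males, n_per_gen, replace = TRUE),
                     sub_genome)
  Hm <- make_gametes(Hpool, sample(pool_females, n_per_gen, replace = TRUE),
                     sub_genome)
  H <- matrix(0L, 2L * n_per_gen, ncol(Hp))
  H[seq(1, 2 * n_per_gen, 2), ] <- Hp
  H[seq(2, 2 * n_per_gen, 2), ] <- Hm
  ix <- dos_range(0)
  ped$id[ix] <- sprintf("G0_%04d", seq_len(n_per_gen))
  ped$generation[ix] <- 0L
  ped$sex[ix] <- sample(rep(c("M", "F"), length.out = n_per_gen))
  dosage[ix, ] <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]

  # TBV scale fixed in generation 0
  raw0 <- as.numeric(dosage[ix, qt, drop = FALSE] %*% map$qtl_effects)
  tbv_center <- mean(raw0)
  tbv_scale <- stats::sd(raw0)
  if (tbv_scale == 0) stop("simulate_breeding(): generation-0 genetic variance is zero")
  tbv <- numeric(n_total)
  tbv[ix] <- (raw0 - tbv_center) / tbv_scale
  sd_e <- sqrt((1 - cfg$h2) / cfg$h2)
  phen_val <- numeric(n_total)
  phen_val[ix] <- tbv[ix] + stats::rnorm(n_per_gen) * sd_e

  # --- breeding generations ----------------------------------------------
  for (g in seq_len(cfg$n_generations)) {
    prev <- dos_range(g - 1L)
    cand_m <- which(ped$sex[prev] == "M")
    cand_f <- which(ped$sex[prev] == "F")
    if (length(cand_m) < cfg$n_sires || length(cand_f) < cfg$n_dams)
      stop("simulate_breeding(): not enough candidates of one sex for selection")
    use_gebv <- cfg$selection == "gebv" && g >= 2
    if (use_gebv) {
      ref <- seq_len((g - 1L) * n_per_gen)  # generations 0 .. g-2 phenotyped
      idx_fit <- c(ref, prev)
      Gm <- build_G(`rownames<-`(dosage[idx_fit, mk, drop = FALSE],
                                 ped$id[idx_fit]), method = cfg$g_method)
      ebv <- solve_blup(Gm, data.frame(id = ped$id[ref],
                                       value = phen_val[ref]), cfg$h2)
      score <- ebv$ebv[match(ped$id[prev], ebv$id)]
      sel_m <- cand_m[order(score[cand_m], decreasing = TRUE)[seq_len(cfg$n_sires)]]
      sel_f <- cand_f[order(score[cand_f], decreasing = TRUE)[seq_len(cfg$n_dams)]]
    } else {
      sel_m <- sample(cand_m, cfg$n_sires)
      sel_f <- sample(cand_f, cfg$n_dams)
    }
    b <- breed_generation(H, sel_m, H, sel_f)
    H <- b$H
    ix <- dos_range(g)
    ped$id[ix] <- sprintf("G%d_%04d", g, seq_len(n_per_gen))
    ped$sire[ix] <- ped$id[prev][sel_m[b$sire]]
    ped$dam[ix] <- ped$id[prev][sel_f[b$dam]]
    ped$generation[ix] <- g
    ped$sex[ix] <- half_sexes(cfg$n_dams, cfg$progeny_per_dam)
    dosage[ix, ] <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]
    raw <- as.numeric(dosage[ix, qt, drop = FALSE] %*% map$qtl_effects)
    tbv[ix] <- (raw - tbv_center) / tbv_scale
    phen_val[ix] <- tbv[ix] + stats::rnorm(n_per_gen) * sd_e
  }

  markers <- dosage[, mk, drop = FALSE]
  dimnames(markers) <- list(ped$id, sprintf("m%05d", map$marker_idx))
  structure(list(pedigree = as_pedigree(ped),
                 markers = markers,
                 tbv = stats::setNames(tbv, ped$id),
                 phen = data.frame(id = ped$id, value = phen_val,
                                   generation = ped$generation,
                                   stringsAsFactors = FALSE),
                 generation = ped$generation,
                 genome = genome, cfg = cfg),
            class = "sim_dataset")
}

#' Write a simulated dataset to a directory
#'
#' Writes pedigree CSV, marker dosage TSV, phenotype TSV, TBV TSV, and a
#' JSON manifest of the configuration.
#'
#' @param sim A [simulate_breeding()] dataset.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_dosages(sim$markers, file.path(dir, "markers.tsv"))
  utils::write.table(sim$phen, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(id = names(sim$tbv), tbv = sim$tbv),
                     file.path(dir, "tbv.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(sim$cfg, list(k = sim$genome$k, L = sim$genome$L,
                              n_loci = length(sim$genome$chr)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
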