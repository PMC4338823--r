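# Synthetic-data generators: biased window sets with analytic ground truth
# and small genomes with planted site clusters, repeat tracks and SNPs.

#' Uniform positional profile
#'
#' Every flank position is uniform over A/C/G/T; the central position is
#' fixed to A, as in every A-centered window.
#'
#' @param radius Flank length in nt.
#' @return A 4 x (2 * radius + 1) column-stochastic matrix (rows A, C, G,
#'   T).
#' @export
uniform_profile <- function(radius) {
  L <- 2L * radius + 1L
  m <- matrix(0.25, nrow = 4, ncol = L, dimnames = list(NUCS, NULL))
  m[, radius + 1L] <- c(1, 0, 0, 0)
  m
}

#' Deaminase-like neighbor-preference profile
#'
#' A positional profile emulating the documented deaminase neighborhood
#' preferences: at the 5' neighbor U(T) and A are favored over G over C,
#' and at the 3' neighbor G is favored, with the bias decaying
#' geometrically away from the central adenosine (scale 3 nt) toward the
#' uniform distribution. `strength` in [0, 1] scales the departure from
#' uniformity; 0 gives [uniform_profile()].
#'
#' @param radius Flank length in nt.
#' @param strength Bias strength in [0, 1].
#' @return A 4 x (2 * radius + 1) column-stochastic matrix.
#' @export
adar_neighbor_profile <- function(radius, strength = 0.6) {
  stopifnot(strength >= 0, strength <= 1)
  L <- 2L * radius + 1L
  m <- matrix(0.25, nrow = 4, ncol = L, dimnames = list(NUCS, NULL))
  five_prime <- c(A = 0.30, C = 0.08, G = 0.17, T = 0.45)  # U ~ A > G > C
  three_prime <- c(A = 0.15, C = 0.12, G = 0.50, T = 0.23) # G-favoring
  for (i in seq_len(L)) {
    off <- i - radius - 1L
    if (off == 0L) next
    base <- if (off < 0) five_prime else three_prime
    decay <- strength * exp(-(abs(off) - 1) / 3)
    m[, i] <- 0.25 + decay * (base - 0.25)
  }
  m[, radius + 1L] <- c(1, 0, 0, 0)
  m
}

#' Specification of a biased synthetic window experiment
#'
#' Bundles the two generating positional profiles, the class sample sizes
#' and the seed. Defaults describe the reference training condition for
#' the editing model: 21-nt windows (radius 10) and 15,140 windows per
#' class -- a 30,280-window dataset split equally between edited and
#' random sites -- with a deaminase-like edited profile against a uniform
#' background.
#'
#' @param radius Flank length in nt.
#' @param edited_profile,unedited_profile 4 x (2 * radius + 1)
#'   column-stochastic matrices (rows A, C, G, T); central column must put
#'   probability 1 on A.
#' @param n_pos,n_neg Windows per class.
#' @param seed Integer seed.
#' @return Object of class `"bias_spec"`.
#' @export
bias_spec <- function(radius = 10,
                      edited_profile = adar_neighbor_profile(radius),
                      unedited_profile = uniform_profile(radius),
                      n_pos = 15140, n_neg = 15140, seed = 42) {
  check_profile <- function(m, what) {
    L <- 2L * radius + 1L
    if (!is.matrix(m) || nrow(m) != 4 || ncol(m) != L) {
      abort(paste0(what, " must be a 4 x ", L, " matrix"), "spec_error")
    }
    if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-9)) {
      abort(paste0(what, " columns must be probability distributions"),
            "spec_error")
    }
    if (abs(m["A", radius + 1L] - 1) > 1e-9) {
      abort(paste0(what, " must fix the central position to A"), "spec_error")
    }
  }
  rownames(edited_profile) <- rownames(unedited_profile) <- NUCS
  check_profile(edited_profile, "edited_profile")
  check_profile(unedited_profile, "unedited_profile")
  stopifnot(n_pos >= 1, n_neg >= 1)
  structure(list(radius = radius, edited_profile = edited_profile,
                 unedited_profile = unedited_profile,
                 n_pos = n_pos, n_neg = n_neg, seed = seed),
            class = "bias_spec")
}

#' Generate labeled window sets from a bias specification
#'
#' Each window is sampled position-independently from its class profile --
#' exactly the independence structure the logistic model assumes, so the
#' generating profiles are the analytic ground truth for profile-recovery
#' and classification checks. Deterministic given `spec$seed`.
#'
#' @param spec A [bias_spec()].
#' @return List with `pos` and `neg` character vectors of lengths
#'   `n_pos` / `n_neg`.
#' @export
generate_window_sets <- function(spec) {
  stopifnot(inherits(spec, "bias_spec"))
  with_seed(spec$seed, {
    list(pos = sample_windows_from(spec$edited_profile, spec$n_pos),
         neg = sample_windows_from(spec$unedited_profile, spec$n_neg))
  })
}

sample_windows_from <- function(profile, n) {
  L <- ncol(profile)
  cols <- lapply(seq_len(L), function(i) {
    p <- profile[, i]
    if (max(p) >= 1 - 1e-12) rep(NUCS[which.max(p)], n)
    else sample(NUCS, n, replace = TRUE, prob = p)
  })
  do.call(paste0, cols)
}

#' Generate a genome with planted editing-site clusters
#'
#' Builds random contigs and plants editing sites in clusters: within a
#' cluster, consecutive-site gaps are geometric with mean
#' `cluster_gap_mean`; clusters are separated by gaps drawn uniformly from
#' 20-40 times that mean, so any segmentation threshold between the two
#' scales recovers the planted clusters exactly. Each cluster lies on one
#' strand; the genome is edited so every site's reference base is A on the
#' forward strand or T on the reverse. Repeat intervals are laid down to
#' cover approximately `repeat_fraction` of each contig, and a share of
#' sites is copied into a SNP track.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in nt.
#' @param n_sites Total sites to plant.
#' @param cluster_gap_mean Mean within-cluster gap in nt.
#' @param sites_per_cluster Mean cluster size (cluster sizes are drawn
#'   1 + Poisson).
#' @param repeat_fraction Approximate fraction of each contig covered by
#'   repeat intervals.
#' @param snp_fraction Fraction of sites duplicated into the SNP track.
#' @param seed Integer seed.
#' @return List with `genome` (named character), `sites`, `repeats`,
#'   `snps` (data.frames on the package's 0-based conventions) and
#'   `truth`: the generator's ledger with `clusters` (one row per planted
#'   cluster) and `site_cluster` (cluster id per site row).
#' @export
generate_genome_with_sites <- function(n_contigs = 2, contig_length = 50000,
                                       n_sites = 80, cluster_gap_mean = 30,
                                       sites_per_cluster = 8,
                                       repeat_fraction = 0.2,
                                       snp_fraction = 0.2, seed = 42) {
  stopifnot(n_contigs >= 1, contig_length > 0, n_sites >= 1,
            cluster_gap_mean >= 1, repeat_fraction >= 0, repeat_fraction < 1,
            snp_fraction >= 0, snp_fraction <= 1)
  with_seed(seed, {
    genome <- lapply(seq_len(n_contigs), function(i) {
      sample(NUCS, contig_length, replace = TRUE)
    })
    names(genome) <- paste0("ctg", seq_len(n_contigs))
    # partition sites into clusters
    sizes <- integer(0)
    while (sum(sizes) < n_sites) {
      sizes <- c(sizes, 1L + stats::rpois(1, sites_per_cluster - 1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - n_sites)
    sizes <- sizes[sizes > 0]
    clusters <- list()
    site_rows <- list()
    ctg <- 1L
    cursor <- round(stats::runif(1, 50, 200))
    for (k in seq_along(sizes)) {
      gaps <- 1L + stats::rgeom(sizes[k] - 1L, 1 / cluster_gap_mean)
      span <- sum(gaps)
      if (cursor + span + 60 > contig_length) {
        ctg <- ctg + 1L
        cursor <- round(stats::runif(1, 50, 200))
        if (ctg > n_contigs || cursor + span + 60 > contig_length) {
          abort("could not place all clusters: contigs too short for the requested sites",
                "generation_error")
        }
      }
      pos <- cursor + c(0L, cumsum(gaps))
      strand <- sample(c("+", "-"), 1)
      genome[[ctg]][pos + 1L] <- if (strand == "+") "A" else "T"
      clusters[[k]] <- data.frame(cluster = k, chrom = names(genome)[ctg],
                                  strand = strand, start = pos[1],
                                  end = pos[length(pos)],
                                  n_sites = length(pos))
      site_rows[[k]] <- data.frame(chrom = names(genome)[ctg], pos = pos,
                                   strand = strand, cluster = k,
                                   stringsAsFactors = FALSE)
      cursor <- pos[length(pos)] +
        round(stats::runif(1, 20, 40) * cluster_gap_mean)
    }
    sites <- do.call(rbind, site_rows)
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
    # repeat track: fixed-length intervals at random starts until covered
    repeats <- list()
    if (repeat_fraction > 0) {
      rep_len_nt <- 400L
      n_rep <- ceiling(repeat_fraction * contig_length / rep_len_nt)
      for (i in seq_len(n_contigs)) {
        starts <- sort(sample.int(contig_length - rep_len_nt, n_rep))
        repeats[[i]] <- data.frame(chrom = names(genome)[i], start = starts,
                                   end = starts + rep_len_nt,
                                   stringsAsFactors = FALSE)
      }
    }
    repeats <- if (length(repeats)) do.call(rbind, repeats) else
      data.frame(chrom = character(), start = integer(), end = integer())
    n_snp <- round(snp_fraction * nrow(sites))
    snp_idx <- if (n_snp > 0) sort(sample.int(nrow(sites), n_snp)) else
      integer(0)
    snps <- sites[snp_idx, c("chrom", "pos"), drop = FALSE]
    rownames(snps) <- NULL
    list(genome = vapply(genome, paste, "", collapse = ""),
         sites = sites[, c("chrom", "pos", "strand")],
         repeats = repeats, snps = snps,
         truth = list(clusters = do.call(rbind, clusters),
                      site_cluster = sites$cluster),
         params = list(n_contigs = n_contigs, contig_length = contig_length,
                       cluster_gap_mean = cluster_gap_mean, seed = seed))
  })
}
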