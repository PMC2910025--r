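# Synthetic kinase-inhibitor panel generator: kinase-like sequences with
# group structure, a ligand descriptor table with low-rank latent
# structure, and a censored pK_d interaction matrix with planted
# additive + bilinear cross effects.

# background residue composition (roughly proteome-average frequencies)
.BG_FREQ <- c(
  A = 0.082, C = 0.014, D = 0.054, E = 0.067, F = 0.039, G = 0.071,
  H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.041,
  P = 0.047, Q = 0.039, R = 0.055, S = 0.067, T = 0.053, V = 0.069,
  W = 0.011, Y = 0.030
)

# residue sets whose enrichment distinguishes the kinase groups
.GROUP_TILT_SETS <- list(
  c("K", "R", "E"), c("S", "T", "N"), c("L", "I", "V"), c("F", "Y", "W"),
  c("G", "P", "D"), c("A", "Q", "H"), c("M", "C", "T")
)

.GROUP_NAMES <- c("AGC", "CAMK", "CK1", "CMGC", "STE", "TK", "TKL")

#' Configuration of the synthetic kinase-inhibitor panel
#'
#' Collects and validates every knob of the generator. Defaults emulate the
#' shape of a kinome-wide primary-screen panel: 317 kinases in 7 groups
#' crossed with 38 inhibitors, kinase-domain lengths mostly 240-300
#' residues with tails to 194 and 606, about 24.8% interacting pairs with
#' measured pK_d in \[5, 10.62\], non-interacting pairs floored at
#' pK_d = 4, and a kinase x ligand cross effect that carries more variance
#' than the additive kinase and ligand effects combined with it.
#'
#' @param n_kinases,n_inhibitors,n_groups Panel dimensions.
#' @param seq_length_range Central range of sequence lengths (most
#'   sequences fall here).
#' @param length_tails Extreme minimum and maximum lengths (rare).
#' @param motif_length Length of each group's fully conserved motif.
#' @param group_tilt Enrichment factor of each group's characteristic
#'   residues over the shared background composition.
#' @param core_length Length of the alignable catalytic core shared by all
#'   sequences (flanking extensions make up the rest of each sequence and
#'   are gap-filtered away in the alignment path).
#' @param conservation Probability that a core position carries the group
#'   consensus residue rather than an individual background substitution.
#' @param group_divergence Fraction of core positions at which a group's
#'   consensus differs from the shared ancestral consensus.
#' @param n_ligand_descriptors Width of the generated ligand table.
#' @param active_fraction_target Desired fraction of pairs at or above the
#'   detection threshold.
#' @param pkd_active_range Span of measurable pK_d values.
#' @param pkd_floor Value recorded for pairs inactive in the primary
#'   screen.
#' @param noise_sd Assay noise, in pK_d units.
#' @param interaction_weight Standard deviation of the planted kinase x
#'   ligand cross effect (pK_d units).
#' @param seed Integer seed; everything the generator does is a
#'   deterministic function of the configuration.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_kinases = 317, n_inhibitors = 38, n_groups = 7,
                         seq_length_range = c(240, 300),
                         length_tails = c(194, 606),
                         motif_length = 5, group_tilt = 2.5,
                         core_length = 170, conservation = 0.7,
                         group_divergence = 0.35,
                         n_ligand_descriptors = 150,
                         active_fraction_target = 0.248,
                         pkd_active_range = c(5.0, 10.62),
                         pkd_floor = 4.0, noise_sd = 0.3,
                         interaction_weight = 1.6, seed = 1) {
  cfg <- list(
    n_kinases = as.integer(n_kinases),
    n_inhibitors = as.integer(n_inhibitors),
    n_groups = as.integer(n_groups),
    seq_length_range = seq_length_range,
    length_tails = length_tails,
    motif_length = as.integer(motif_length),
    group_tilt = group_tilt,
    core_length = as.integer(core_length),
    conservation = conservation,
    group_divergence = group_divergence,
    n_ligand_descriptors = as.integer(n_ligand_descriptors),
    active_fraction_target = active_fraction_target,
    pkd_active_range = pkd_active_range,
    pkd_floor = pkd_floor,
    noise_sd = noise_sd,
    interaction_weight = interaction_weight,
    seed = as.integer(seed)
  )
  if (cfg$n_groups < 1) stop("n_groups must be >= 1", call. = FALSE)
  if (cfg$pkd_floor >= cfg$pkd_active_range[1]) {
    stop("pkd_floor must lie below the active pK_d range", call. = FALSE)
  }
  if (cfg$active_fraction_target <= 0 || cfg$active_fraction_target >= 1) {
    stop("active_fraction_target must be in (0, 1)", call. = FALSE)
  }
  min_len <- min(cfg$seq_length_range[1], cfg$length_tails[1])
  if (cfg$motif_length >= min_len) {
    stop("motif_too_long: motif must be shorter than the shortest sequence",
         call. = FALSE)
  }
  if (cfg$motif_length >= cfg$core_length) {
    stop("motif_too_long: motif must fit inside the conserved core",
         call. = FALSE)
  }
  if (cfg$core_length > min_len) {
    stop("core_length must not exceed the shortest sequence length",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# draw one sequence length: mostly in the central range, rare tails
.draw_lengths <- function(n, cfg) {
  lo <- cfg$seq_length_range[1]; hi <- cfg$seq_length_range[2]
  mid <- round((lo + hi) / 2)
  bucket <- sample(1:4, n, replace = TRUE,
                   prob = c(0.55, 0.35, 0.06, 0.04))
  len <- integer(n)
  len[bucket == 1] <- sample(lo:mid, sum(bucket == 1), replace = TRUE)
  len[bucket == 2] <- sample(mid:hi, sum(bucket == 2), replace = TRUE)
  len[bucket == 3] <- sample(cfg$length_tails[1]:lo, sum(bucket == 3),
                             replace = TRUE)
  len[bucket == 4] <- sample(hi:cfg$length_tails[2], sum(bucket == 4),
                             replace = TRUE)
  len
}

#' Generate kinase-like sequences with planted group structure
#'
#' Produces `n_kinases` sequences over the 20-letter amino-acid alphabet,
#' assigned round-robin to `n_groups` groups. Sequences follow a star
#' phylogeny: every sequence shares an alignable catalytic core of
#' `core_length` residues derived from one ancestral consensus; each
#' group's consensus diverges from it at a `group_divergence` fraction of
#' positions (drawn from a group-tilted composition), and each kinase
#' copies its group consensus with per-position probability `conservation`,
#' substituting background residues elsewhere. A fully conserved
#' `motif_length`-residue group motif sits at a group-specific core
#' position (+/-2 residues of jitter), and unconserved flanking extensions
#' carry each sequence to its drawn length. The emitted multiple alignment
#' anchors the cores and pads the flanks with `-`; gap-filtering therefore
#' reduces the alignment to (roughly) the core, as with real kinase-domain
#' alignments. A trivially constructed
#' multiple alignment (sequences anchored at their motif and padded with
#' `-`) is emitted alongside for the alignment-based description path.
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `kinase`, `group`, `sequence` and
#'   `aligned`; planted motifs and anchors are stored in the `"truth"`
#'   attribute.
#' @export
generate_sequences <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    groups <- rep_len(seq_len(cfg$n_groups), cfg$n_kinases)
    group_names <- if (cfg$n_groups <= length(.GROUP_NAMES)) {
      .GROUP_NAMES[seq_len(cfg$n_groups)]
    } else {
      c(.GROUP_NAMES,
        paste0("G", seq(length(.GROUP_NAMES) + 1, cfg$n_groups)))
    }
    # group-specific residue composition: shared background, fixed tilt
    comp <- lapply(seq_len(cfg$n_groups), function(g) {
      tilt_set <- .GROUP_TILT_SETS[[((g - 1) %% length(.GROUP_TILT_SETS)) + 1]]
      f <- .BG_FREQ
      f[tilt_set] <- f[tilt_set] * cfg$group_tilt
      f / sum(f)
    })
    # distinct conserved motifs
    motifs <- character(cfg$n_groups)
    repeat {
      motifs <- vapply(seq_len(cfg$n_groups), function(g) {
        paste(sample(AA_ALPHABET, cfg$motif_length, replace = TRUE,
                     prob = comp[[g]]), collapse = "")
      }, character(1))
      if (!anyDuplicated(motifs)) break
    }
    # star phylogeny for the catalytic core: a shared ancestral consensus,
    # group consensuses diverged from it, individual sequences partially
    # conserved copies of their group consensus
    lc <- cfg$core_length
    ancestor <- sample(AA_ALPHABET, lc, replace = TRUE, prob = .BG_FREQ)
    anchor_frac <- seq(0.25, 0.75, length.out = max(cfg$n_groups, 2))
    motif_at <- pmax(1, pmin(round(anchor_frac * (lc - cfg$motif_length)) + 1,
                             lc - cfg$motif_length + 1))
    consensus <- lapply(seq_len(cfg$n_groups), function(g) {
      cons <- ancestor
      mut <- stats::runif(lc) < cfg$group_divergence
      cons[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE,
                          prob = comp[[g]])
      cons[motif_at[g]:(motif_at[g] + cfg$motif_length - 1)] <-
        strsplit(motifs[g], "")[[1]]
      cons
    })
    lens <- pmax(.draw_lengths(cfg$n_kinases, cfg), lc)
    starts <- integer(cfg$n_kinases)
    left <- integer(cfg$n_kinases)
    seqs <- character(cfg$n_kinases)
    for (i in seq_len(cfg$n_kinases)) {
      g <- groups[i]
      len <- lens[i]
      core <- consensus[[g]]
      mut <- stats::runif(lc) >= cfg$conservation
      core[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE,
                          prob = comp[[g]])
      # the group motif stays fully conserved, with a little positional
      # jitter realised by shifting it inside the core
      s <- motif_at[g] + sample(-2:2, 1)
      s <- min(max(s, 1), lc - cfg$motif_length + 1)
      core[s:(s + cfg$motif_length - 1)] <- strsplit(motifs[g], "")[[1]]
      # unconserved flanking extensions carry the remaining length
      flank_total <- len - lc
      nl_left <- if (flank_total > 0) sample(0:flank_total, 1) else 0L
      nl_right <- flank_total - nl_left
      chars <- c(
        sample(AA_ALPHABET, nl_left, replace = TRUE, prob = comp[[g]]),
        core,
        sample(AA_ALPHABET, nl_right, replace = TRUE, prob = comp[[g]])
      )
      left[i] <- nl_left
      starts[i] <- nl_left + s
      seqs[i] <- paste(chars, collapse = "")
    }
    # anchored alignment: core start columns coincide; flanks pad with gaps
    off <- max(left) - left
    width <- max(off + lens)
    aligned <- vapply(seq_len(cfg$n_kinases), function(i) {
      paste0(strrep("-", off[i]), seqs[i],
             strrep("-", width - off[i] - lens[i]))
    }, character(1))
    out <- tibble::tibble(
      kinase = sprintf("kin%03d", seq_len(cfg$n_kinases)),
      group = group_names[groups],
      sequence = seqs,
      aligned = aligned
    )
    attr(out, "truth") <- list(motifs = motifs, motif_start = starts,
                               group_index = groups,
                               composition = comp)
    out
  })
}

#' Generate a synthetic ligand descriptor table
#'
#' Builds an `n_inhibitors` x `n_ligand_descriptors` numeric table in which
#' a three-dimensional ligand latent vector is embedded (with noise) in a
#' subset of columns while the remaining columns are independent noise —
#' the low-rank-plus-noise structure typical of large molecular descriptor
#' sets. The latent vectors and per-compound additive activity effects are
#' stored in the `"truth"` attribute for downstream activity generation.
#'
#' @param config A [synth_config()].
#' @return A tibble with column `compound` followed by descriptor columns
#'   `D001`, `D002`, ...
#' @export
generate_ligand_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_inhibitors; p <- cfg$n_ligand_descriptors
    # sparse non-negative recognition features: a compound either carries a
    # recognition feature strongly or not at all (selective chemotypes)
    q <- 4L
    v <- matrix(stats::rexp(n * q) * (stats::runif(n * q) < 0.35), n, q)
    b <- stats::rnorm(n, sd = 0.8)
    n_signal <- min(p, max(q, round(p / 5)))
    load <- matrix(stats::rnorm(q * n_signal), q, n_signal)
    mat <- matrix(stats::rnorm(n * p), n, p)
    if (n_signal > 0) {
      mat[, seq_len(n_signal)] <- v %*% load +
        0.3 * mat[, seq_len(n_signal), drop = FALSE]
    }
    colnames(mat) <- sprintf("D%03d", seq_len(p))
    out <- dplyr::bind_cols(
      tibble::tibble(compound = sprintf("inh%02d", seq_len(n))),
      tibble::as_tibble(mat)
    )
    attr(out, "truth") <- list(v = v, ligand_effect = b)
    attr(out, "block_tag") <- "ligand"
    out
  })
}

#' Generate the censored pK_d interaction matrix
#'
#' Plants the activity surface
#' pK_d(k, l) = mu + a_k + b_l + u_k' M v_l + eps, where a_k is a
#' group-level kinase effect with small per-kinase jitter, b_l the
#' compound's promiscuity effect, u_k a group-level latent vector (with
#' small per-kinase jitter), v_l the ligand latent vector embedded in the
#' descriptor table, and eps ~ N(0, `noise_sd`). The latent factors are
#' non-negative and sparse — each compound carries a few recognition
#' features, each group responds to a few — so matching pairs *gain*
#' affinity while mismatches stay flat, giving the latent surface the short
#' sub-threshold tail and long right tail of a detection-limited binding
#' screen. The cross effect is double-centred (orthogonal to the additive
#' row/column effects) and scaled to standard deviation
#' `interaction_weight`, so with the default it carries clearly more
#' variance than the additive part — selectivity dominates over average
#' promiscuity. The intercept mu is calibrated by bisection so
#' the fraction of pairs at or above the detection threshold (the lower end
#' of `pkd_active_range`) matches `active_fraction_target` to within 0.01.
#' Censoring happens after noise: cells below the threshold are recorded as
#' `pkd_floor` with `inactive = TRUE`; active cells are clipped to
#' `pkd_active_range`.
#'
#' @param sequences Output of [generate_sequences()].
#' @param ligand_table Output of [generate_ligand_table()].
#' @param config The same [synth_config()] used for both.
#' @return A long tibble with columns `kinase`, `compound`, `pkd`,
#'   `inactive`; the planted parameters and the uncensored matrix are in
#'   the `"truth"` attribute.
#' @export
generate_activity_matrix <- function(sequences, ligand_table, config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  if (nrow(sequences) != cfg$n_kinases ||
      nrow(ligand_table) != cfg$n_inhibitors) {
    stop("sequences/ligand_table dimensions do not match the config",
         call. = FALSE)
  }
  seq_truth <- attr(sequences, "truth")
  lig_truth <- attr(ligand_table, "truth")
  if (is.null(seq_truth) || is.null(lig_truth)) {
    stop("inputs must come from the paired generator functions",
         call. = FALSE)
  }
  withr::with_seed(cfg$seed + 2L, {
    nk <- cfg$n_kinases; nl <- cfg$n_inhibitors
    g_idx <- seq_truth$group_index
    v <- lig_truth$v
    q <- ncol(v)
    # concentrated non-negative group profiles: each group recognises
    # mainly one or two latent pharmacophore axes, so matching
    # (group, compound) pairs gain affinity while mismatches stay flat
    u_g <- matrix(stats::rexp(cfg$n_groups * q)^2, cfg$n_groups, q)
    u_g <- u_g / rowSums(u_g)
    u <- u_g[g_idx, , drop = FALSE] +
      0.05 * abs(matrix(stats::rnorm(nk * q), nk, q))
    m_mat <- diag(q) + 0.3 * matrix(abs(stats::rnorm(q * q)), q, q)
    inter <- u %*% m_mat %*% t(v)
    # double-centre so the cross effect is orthogonal to the additive
    # row/column effects; the sparse positive hits keep its long right tail
    inter <- sweep(sweep(inter, 1, rowMeans(inter)), 2, colMeans(inter)) +
      mean(inter)
    s <- stats::sd(as.vector(inter))
    if (s > 0) inter <- inter * (cfg$interaction_weight / s)
    alpha_g <- stats::rnorm(cfg$n_groups, sd = 0.4)
    # per-kinase offsets (individual ATP-pocket idiosyncrasies, mutations):
    # exploitable when the kinase is seen in training, pure noise otherwise
    a_k <- alpha_g[g_idx] + stats::rnorm(nk, sd = 0.35)
    b_l <- lig_truth$ligand_effect
    eps <- matrix(stats::rnorm(nk * nl, sd = cfg$noise_sd), nk, nl)
    base <- outer(a_k, b_l, "+") + inter + eps
    thr <- cfg$pkd_active_range[1]
    target <- cfg$active_fraction_target
    lo <- thr - max(base) - 1; hi <- thr - min(base) + 1
    for (it in 1:60) {
      mu <- (lo + hi) / 2
      frac <- mean(base + mu >= thr)
      if (abs(frac - target) <= 0.005) break
      if (frac < target) lo <- mu else hi <- mu
    }
    pkd_unc <- base + mu
    active <- pkd_unc >= thr
    pkd <- ifelse(active, pmin(pkd_unc, cfg$pkd_active_range[2]),
                  cfg$pkd_floor)
    dimnames(pkd_unc) <- dimnames(pkd) <-
      list(sequences$kinase, ligand_table$compound)
    out <- tibble::tibble(
      kinase = rep(sequences$kinase, times = nl),
      compound = rep(ligand_table$compound, each = nk),
      pkd = as.vector(pkd),
      inactive = as.vector(!active)
    )
    attr(out, "truth") <- list(
      mu = mu, kinase_effect = a_k, ligand_effect = b_l,
      interaction = inter, u = u, v = v, m = m_mat,
      pkd_uncensored = pkd_unc,
      active_fraction = mean(active)
    )
    out
  })
}

#' Simulate a complete synthetic kinase-inhibitor panel
#'
#' Runs the three generator stages with one configuration and returns the
#' bundle: sequences (with alignment), ligand table, censored activity
#' table, and the planted truth.
#'
#' @param config A [synth_config()]; defaults emulate a 317 x 38 panel.
#' @return A list of class `pcm_panel` with elements `sequences`,
#'   `ligand_table`, `activity`, `truth` and `config`.
#' @export
#' @examples
#' panel <- simulate_kinome_panel(synth_config(n_kinases = 14,
#'                                             n_inhibitors = 6,
#'                                             n_ligand_descriptors = 20,
#'                                             seed = 7))
#' panel$activity
simulate_kinome_panel <- function(config = synth_config()) {
  sequences <- generate_sequences(config)
  ligand_table <- generate_ligand_table(config)
  activity <- generate_activity_matrix(sequences, ligand_table, config)
  structure(
    list(sequences = sequences, ligand_table = ligand_table,
         activity = activity,
         truth = c(attr(activity, "truth"),
                   attr(sequences, "truth")["motifs"]),
         config = config),
    class = "pcm_panel"
  )
}

#' @export
print.pcm_panel <- function(x, ...) {
  cat(sprintf(
    "synthetic panel: %d kinases (%d groups) x %d inhibitors; %.1f%% active\n",
    x$config$n_kinases, x$config$n_groups, x$config$n_inhibitors,
    100 * x$truth$active_fraction))
  invisible(x)
}

#' Write a synthetic panel to plain-text files
#'
#' Writes the unaligned and aligned sequences as FASTA, the ligand table
#' and the activity matrix as TSV (entity ids in the first column), and
#' the configuration as JSON.
#'
#' @param panel A `pcm_panel` from [simulate_kinome_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "pcm_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::AAStringSet(
    stats::setNames(panel$sequences$sequence, panel$sequences$kinase))
  aln <- Biostrings::AAStringSet(
    stats::setNames(panel$sequences$aligned, panel$sequences$kinase))
  paths <- file.path(dir, c("kinases.fasta", "kinases_aligned.fasta",
                            "ligand_descriptors.tsv", "activity.tsv",
                            "config.json"))
  Biostrings::writeXStringSet(seqs, paths[1])
  Biostrings::writeXStringSet(aln, paths[2])
  readr::write_tsv(panel$ligand_table, paths[3])
  wide <- tidyr::pivot_wider(panel$activity[c("kinase", "compound", "pkd")],
                             names_from = "compound", values_from = "pkd")
  readr::write_tsv(wide, paths[4])
  writeLines(jsonlite::toJSON(unclass(panel$config), auto_unbox = TRUE,
                              pretty = TRUE), paths[5])
  invisible(paths)
}
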