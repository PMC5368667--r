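#' Deterministic RNG substream seed
#'
#' Splits one master seed into independent substreams by a Lehmer-style
#' multiplicative step per index, so generating replicate k never depends
#' on how many replicates precede it. All generator randomness flows
#' through this.
#'
#' @param seed Master integer seed.
#' @param ... Integer indices identifying the substream (construct,
#'   replicate, ...).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (idx in c(...)) {
    # 16807 * 2^31 < 2^53: exact in double arithmetic
    s <- (16807 * ((s + as.numeric(idx) + 1) %% 2147483647)) %% 2147483647
  }
  as.integer(max(1, s))
}

#' Titration ground truth
#'
#' Forward model for synthetic yeast-display titrations: the saturation
#' binding isotherm plus linear nonspecific signal ([binding_model()])
#' with additive Gaussian noise. The default concentration ladder is 10
#' half-log steps bracketing K_D (good titration design).
#'
#' @param kd True dissociation constant (M).
#' @param apc_min,apc_sat,apc_ns Model parameters (a.u., a.u., a.u./M).
#' @param concentrations Molar ladder; default brackets `kd`.
#' @param noise_sd Gaussian signal noise SD (a.u.).
#' @param n_replicates Number of replicate titrations.
#' @param seed Integer seed.
#' @return List of class `titration_truth`.
#' @export
titration_truth <- function(kd,
                            apc_min = 150,
                            apc_sat = 2000,
                            apc_ns = 1e7,
                            concentrations = NULL,
                            noise_sd = 40,
                            n_replicates = 3L,
                            seed = 1L) {
  stopifnot(kd > 0, noise_sd >= 0, n_replicates >= 1L)
  if (is.null(concentrations)) {
    concentrations <- kd * 10^seq(-2.25, 2.25, by = 0.5)
  }
  structure(list(kd = kd, apc_min = apc_min, apc_sat = apc_sat,
                 apc_ns = apc_ns, concentrations = sort(concentrations),
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "titration_truth")
}

#' Generate replicate titrations from a known truth
#'
#' @param truth [titration_truth()].
#' @return List of `n_replicates` data frames (`conc`, `signal`);
#'   identical for identical `(truth, seed)`.
#' @export
gen_titration <- function(truth) {
  stopifnot(inherits(truth, "titration_truth"))
  mu <- binding_model(truth$concentrations, truth$apc_min, truth$apc_sat,
                      truth$apc_ns, truth$kd)
  lapply(seq_len(truth$n_replicates), function(r) {
    set.seed(stream_seed(truth$seed, 101L, r))
    data.frame(conc = truth$concentrations,
               signal = mu + stats::rnorm(length(mu), 0, truth$noise_sd))
  })
}

#' Melt-curve ground truth
#'
#' Forward model for synthetic CD melts: two-state van't Hoff unfolding
#' with zero heat-capacity change, `dG(T) = dH * (1 - T/Tm)` (absolute
#' temperatures), `f(T) = 1 / (1 + exp(-dG / (R T)))`, sloped linear
#' folded/unfolded baselines, and additive Gaussian ellipticity noise. At
#' `T = Tm` the noiseless signal sits exactly midway between the
#' baselines. This is the simplest forward model whose inverse is the
#' baseline/fraction-folded analysis; the enthalpy is a generator knob,
#' never estimated from data.
#'
#' @param tm True melting temperature (deg C), inside the grid span.
#' @param dh Van't Hoff enthalpy (kJ/mol, > 0); larger values sharpen the
#'   transition.
#' @param folded_baseline,unfolded_baseline `c(slope, intercept)` in
#'   mdeg/degC and mdeg.
#' @param temp_grid Temperature grid (deg C, default 25-95 by 0.5).
#' @param noise_sd Gaussian noise SD (mdeg).
#' @param reversibility Amplitude fraction retained by the repeat scan;
#'   `NA` to generate first scans only.
#' @param n_replicates Number of replicate melts.
#' @param seed Integer seed.
#' @return List of class `melt_truth`.
#' @export
melt_truth <- function(tm,
                       dh = 400,
                       folded_baseline = c(-0.01, -2),
                       unfolded_baseline = c(-0.002, -14),
                       temp_grid = seq(25, 95, by = 0.5),
                       noise_sd = 0.3,
                       reversibility = NA_real_,
                       n_replicates = 2L,
                       seed = 1L) {
  stopifnot(dh > 0, noise_sd >= 0,
            tm > min(temp_grid), tm < max(temp_grid))
  structure(list(tm = tm, dh = dh,
                 folded_baseline = folded_baseline,
                 unfolded_baseline = unfolded_baseline,
                 temp_grid = temp_grid, noise_sd = noise_sd,
                 reversibility = reversibility,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "melt_truth")
}

#' Noiseless two-state melt signal
#'
#' @param truth [melt_truth()].
#' @param temp Temperatures (deg C).
#' @return List with `fraction` and `signal` at `temp`.
#' @export
melt_forward <- function(truth, temp = truth$temp_grid) {
  R <- 8.314462618 # J/mol/K
  tk <- temp + 273.15
  tmk <- truth$tm + 273.15
  dg <- truth$dh * 1000 * (1 - tk / tmk)
  f <- 1 / (1 + exp(-dg / (R * tk)))
  thf <- truth$folded_baseline[2] + truth$folded_baseline[1] * temp
  thu <- truth$unfolded_baseline[2] + truth$unfolded_baseline[1] * temp
  list(fraction = f, signal = f * thf + (1 - f) * thu)
}

#' Generate replicate melts from a known truth
#'
#' @param truth [melt_truth()]. Replicate r of a first scan uses RNG
#'   substream `(201, r)`; repeat scans use `(202, r)`.
#' @param replicate_seeds Optional explicit integer seeds, one per
#'   replicate, overriding the substream derivation (e.g. to pin
#'   replicates to seeds 1 and 2).
#' @return List of replicates, each `list(first = data.frame(temp,
#'   signal), second = ... or NULL)`.
#' @export
gen_melt <- function(truth, replicate_seeds = NULL) {
  stopifnot(inherits(truth, "melt_truth"))
  fw <- melt_forward(truth)
  lapply(seq_len(truth$n_replicates), function(r) {
    s1 <- if (is.null(replicate_seeds)) stream_seed(truth$seed, 201L, r)
          else replicate_seeds[r]
    set.seed(s1)
    first <- data.frame(
      temp = truth$temp_grid,
      signal = fw$signal + stats::rnorm(length(fw$signal), 0, truth$noise_sd))
    second <- NULL
    if (!is.na(truth$reversibility)) {
      thu <- truth$unfolded_baseline[2] +
        truth$unfolded_baseline[1] * truth$temp_grid
      set.seed(stream_seed(s1, 202L, r))
      second <- data.frame(
        temp = truth$temp_grid,
        signal = thu + truth$reversibility * (fw$signal - thu) +
          stats::rnorm(length(fw$signal), 0, truth$noise_sd))
    }
    list(first = first, second = second)
  })
}

#' Trajectory ground truth
#'
#' Forward model for synthetic probe trajectories: frames are independent
#' samples (the downstream analysis treats them as such, so no dynamics
#' are simulated). Per frame each probe is independently placed either
#' uniformly in a thin shell around a randomly chosen designated
#' "hydrophobic" atom, or uniformly in the box at least
#' `min_protein_dist` from every protein atom. The shell-placement odds
#' are `(enrichment - 1) * n_designated * V_cutoff / V_box`, chosen so
#' the `enrichment` parameter equals the expected ratio of local probe
#' density at designated atoms to the bulk background (`enrichment = 1`
#' recovers uniform placement). Probe count (80) and shell geometry echo
#' methane-probe hydrophobicity-mapping conventions; this emulates, not
#' simulates, hydrophobic attraction.
#'
#' @param protein `n x 3` matrix of protein atom coordinates (nm),
#'   or `NULL` for a default 27-atom grid cluster centered in the box.
#' @param designated Indices of protein atoms designated hydrophobic.
#' @param n_probes Number of probe particles (default 80).
#' @param enrichment Local density enrichment factor (`>= 1`).
#' @param n_frames Number of frames.
#' @param box Cubic box edge or `c(x, y, z)` (nm).
#' @param shell Shell radii `c(inner, outer)` around designated atoms (nm).
#' @param min_protein_dist Exclusion distance for background placements (nm).
#' @param seed Integer seed.
#' @return List of class `trajectory_truth`.
#' @export
trajectory_truth <- function(protein = NULL,
                             designated = integer(0),
                             n_probes = 80L,
                             enrichment = 1,
                             n_frames = 200L,
                             box = 6,
                             shell = c(0.35, 0.5),
                             min_protein_dist = 0.35,
                             seed = 1L) {
  if (length(box) == 1L) box <- rep(box, 3L)
  if (is.null(protein)) {
    g <- seq(-0.5, 0.5, by = 0.5)
    protein <- as.matrix(expand.grid(x = g, y = g, z = g))
    protein <- sweep(protein, 2, box / 2, "+")
  }
  stopifnot(enrichment >= 1, n_probes >= 1L, n_frames >= 1L)
  if (enrichment > 1 && length(designated) == 0L) {
    stop("enrichment > 1 requires a nonempty designated atom set")
  }
  structure(list(protein = protein, designated = as.integer(designated),
                 n_probes = as.integer(n_probes), enrichment = enrichment,
                 n_frames = as.integer(n_frames), box = box, shell = shell,
                 min_protein_dist = min_protein_dist,
                 seed = as.integer(seed)),
            class = "trajectory_truth")
}

runif_shell <- function(center, r1, r2, box) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  r <- (stats::runif(1) * (r2^3 - r1^3) + r1^3)^(1 / 3)
  (center + r * u) %% box
}

#' Generate a synthetic probe trajectory
#'
#' @param truth [trajectory_truth()].
#' @return `vh_trajectory` (protein CA-like atoms plus PRB probe
#'   particles, periodic box); byte-identical for identical inputs.
#' @export
gen_trajectory <- function(truth) {
  stopifnot(inherits(truth, "trajectory_truth"))
  prot <- truth$protein
  np <- nrow(prot)
  box <- truth$box
  v_cut <- (4 / 3) * pi * truth$shell[2]^3
  odds <- (truth$enrichment - 1) * length(truth$designated) * v_cut / prod(box)
  q <- odds / (1 + odds)
  if (any(box < 4 * truth$min_protein_dist)) {
    stop("box too small to place probes away from the protein")
  }
  set.seed(stream_seed(truth$seed, 301L))
  frames <- lapply(seq_len(truth$n_frames), function(fr) {
    probes <- matrix(0, truth$n_probes, 3)
    for (p in seq_len(truth$n_probes)) {
      if (truth$enrichment > 1 && stats::runif(1) < q) {
        ctr <- prot[sample(truth$designated, 1L), ]
        probes[p, ] <- runif_shell(ctr, truth$shell[1], truth$shell[2], box)
      } else {
        repeat {
          x <- stats::runif(3) * box
          if (min(min_image_dist2(x, prot, box)) >=
                truth$min_protein_dist^2) break
        }
        probes[p, ] <- x
      }
    }
    rbind(prot, probes)
  })
  atoms <- data.frame(
    name = c(rep("CA", np), rep("PRB", truth$n_probes)),
    element = "C",
    resid = c(rep("PRO", np), rep("PRB", truth$n_probes)),
    resno = c(seq_len(np), np + seq_len(truth$n_probes)),
    stringsAsFactors = FALSE)
  atoms$is_probe <- atoms$resid == "PRB"
  atoms$is_heavy <- TRUE
  trajectory(frames, atoms, box = box)
}

# ---- synthetic VH maturation lineage -------------------------------------

# Kabat positions and residues of the synthetic wild-type VH stand-in.
# This is a SYNTHETIC sequence: a VH3-like scaffold with the antigen
# peptide graft occupying CDR3 insertions 100-100i, constructed so that
# every residue identity the maturation lineage requires (mutated
# positions, the glycosylation sequon created by D72N, the hydrophobic
# 100e-GIIIA-100i patch exposed by the 100h reversion) is in place. It is
# not a transcription of any deposited antibody sequence.
synthetic_wt_positions <- function() {
  c(as.character(1:82), "82a", "82b", "82c", as.character(83:100),
    paste0("100", letters[1:9]), as.character(101:113))
}

synthetic_wt_residues <- function() {
  strsplit(paste0(
    "EVQLVESGGGLVQPGGSLRLSCAAS", # 1-25
    "GFTFSSYAMSWVRQAPGKG",       # 26-44
    "ELWVS",                     # 45-49 (framework E45)
    "SISGSGGSTYYASSVKG",         # 50-66 (CDR2: S50, S52, S62)
    "RFTI",                      # 67-70
    "RDTSKNTL",                  # 71-78 (CDR4: D72, T73, S74)
    "YLQM",                      # 79-82
    "NSL",                       # 82a-82c (S82b)
    "RAEDTAVYYCAK",              # 83-94
    "KDYED",                     # 95-99 (CDR3 N-terminus, E98)
    "GLMVGGVVIA",                # 100-100i (grafted peptide; G100d, I100h)
    "DYWGQGTLVTVSS"              # 101-113
  ), "")[[1]]
}

#' The synthetic VH affinity-maturation lineage
#'
#' Materializes the wild-type stand-in sequence, the four sequentially
#' evolved variants (P1: L11P, E45K, S82bG, G100dR; P2: + S52H, S62R,
#' D72N; P3: + S50R, I100hT; P4: + E98K, V100fI, V100gI), every
#' single-reversion construct in the context in which each mutation was
#' acquired plus all twelve P4 reversions, and the wild-type scaffold
#' carrying the six key affinity mutations (K45, R50, R62, N72, K98,
#' R100d). Reversion constructs are named `<context>_<reversion>`, e.g.
#' `P4_K45E`.
#'
#' @return Named list of `vh_variant`s.
#' @export
synthetic_vh_lineage <- function() {
  wt <- vh_variant("WT", synthetic_wt_positions(), synthetic_wt_residues())
  p1_muts <- c("L11P", "E45K", "S82bG", "G100dR")
  p2_muts <- c("S52H", "S62R", "D72N")
  p3_muts <- c("S50R", "I100hT")
  p4_muts <- c("E98K", "V100fI", "V100gI")
  p1 <- apply_mutations(wt, p1_muts, name = "P1")
  p2 <- apply_mutations(p1, p2_muts, name = "P2")
  p3 <- apply_mutations(p2, p3_muts, name = "P3")
  p4 <- apply_mutations(p3, p4_muts, name = "P4")
  out <- list(WT = wt, P1 = p1, P2 = p2, P3 = p3, P4 = p4)
  contexts <- list(P1 = list(v = p1, muts = p1_muts),
                   P2 = list(v = p2, muts = p2_muts),
                   P3 = list(v = p3, muts = p3_muts),
                   P4 = list(v = p4, muts = c(p1_muts, p2_muts, p3_muts,
                                              p4_muts)))
  for (cn in names(contexts)) {
    ctx <- contexts[[cn]]
    for (m in ctx$muts) {
      rev <- format(reverse_mutation(m))
      nm <- paste0(cn, "_", rev)
      out[[nm]] <- apply_mutations(ctx$v, rev, name = nm)
    }
  }
  six <- c("E45K", "S50R", "S62R", "D72N", "E98K", "G100dR")
  out$WT6 <- apply_mutations(wt, six, name = "WT6")
  out
}

#' Ground-truth design table for the synthetic maturation study
#'
#' The study conditions the generators emulate: per construct, the true
#' apparent melting temperature (deg C), true dissociation constant (M),
#' whether the titration is measurable at the shared concentration
#' ladder, and - for reversion constructs - the expected qualitative
#' classification of the forward mutation in its context. Lineage
#' variants follow the qualitative maturation pattern: P1 binding below
#' the detection ladder; R62/N72 (acquired in P2) and R50 (P3)
#' affinity-enhancing but destabilizing; K45 (P1) and K98 (P4) enhancing
#' and stabilizing; R100d (P1) the strongest affinity mutation with
#' neutral stability; H52/G82b/I100f/I100g/T100h passengers; the
#' six-affinity-mutation scaffold (WT6) more stable but weaker-binding
#' than P4.
#'
#' @return Data frame: `construct`, `context`, `mutation` (forward, `NA`
#'   for lineage variants), `tm_true`, `kd_true`, `measurable`,
#'   `affinity_class`, `stability_class`.
#' @export
pseries_truths <- function() {
  rec <- function(construct, context, mutation, tm, kd, meas, aff, stab) {
    data.frame(construct = construct, context = context, mutation = mutation,
               tm_true = tm, kd_true = kd, measurable = meas,
               affinity_class = aff, stability_class = stab,
               stringsAsFactors = FALSE)
  }
  na <- NA_character_
  do.call(rbind, list(
    rec("WT",  na, na, 75.0, 1e-3, FALSE, na, na),
    rec("P1",  na, na, 73.2, 1e-3, FALSE, na, na),
    rec("P2",  na, na, 65.5, 5e-7, TRUE,  na, na),
    rec("P3",  na, na, 63.3, 1.5e-7, TRUE, na, na),
    rec("P4",  na, na, 66.0, 2e-8, TRUE,  na, na),
    rec("WT6", na, na, 70.5, 1e-7, TRUE,  na, na),
    # P1-context reversions (context unmeasurable: affinity not-computable)
    rec("P1_P11L",   "P1", "L11P",   74.8, 1e-3, FALSE, "not-computable", "destabilizing"),
    rec("P1_K45E",   "P1", "E45K",   70.9, 1e-3, FALSE, "not-computable", "stabilizing"),
    rec("P1_G82bS",  "P1", "S82bG",  73.2, 1e-3, FALSE, "not-computable", "neutral"),
    rec("P1_R100dG", "P1", "G100dR", 73.2, 1e-3, FALSE, "not-computable", "neutral"),
    # P2-context reversions
    rec("P2_H52S",   "P2", "S52H",   65.5, 5e-7, TRUE,  "neutral",   "neutral"),
    rec("P2_R62S",   "P2", "S62R",   69.5, 1e-3, FALSE, "enhancing", "destabilizing"),
    rec("P2_N72D",   "P2", "D72N",   72.5, 1e-3, FALSE, "enhancing", "destabilizing"),
    # P3-context reversions
    rec("P3_R50S",   "P3", "S50R",   65.5, 6e-7, TRUE,  "enhancing", "destabilizing"),
    rec("P3_T100hI", "P3", "I100hT", 63.3, 1.5e-7, TRUE, "neutral",  "neutral"),
    # P4-context reversions (all twelve)
    rec("P4_P11L",   "P4", "L11P",   68.0, 2e-8, TRUE,  "neutral",   "destabilizing"),
    rec("P4_K45E",   "P4", "E45K",   63.8, 1e-7, TRUE,  "enhancing", "stabilizing"),
    rec("P4_H52S",   "P4", "S52H",   67.8, 2e-8, TRUE,  "neutral",   "destabilizing"),
    rec("P4_R50S",   "P4", "S50R",   68.5, 2e-7, TRUE,  "enhancing", "destabilizing"),
    rec("P4_R62S",   "P4", "S62R",   70.0, 2e-7, TRUE,  "enhancing", "destabilizing"),
    rec("P4_N72D",   "P4", "D72N",   72.9, 1.5e-7, TRUE, "enhancing", "destabilizing"),
    rec("P4_G82bS",  "P4", "S82bG",  66.0, 2e-8, TRUE,  "neutral",   "neutral"),
    rec("P4_K98E",   "P4", "E98K",   62.4, 6e-8, TRUE,  "enhancing", "stabilizing"),
    rec("P4_R100dG", "P4", "G100dR", 66.0, 1e-3, FALSE, "enhancing", "neutral"),
    rec("P4_I100fV", "P4", "V100fI", 66.0, 2e-8, TRUE,  "neutral",   "neutral"),
    rec("P4_I100gV", "P4", "V100gI", 66.0, 2e-8, TRUE,  "neutral",   "neutral"),
    rec("P4_T100hI", "P4", "I100hT", 66.0, 2e-8, TRUE,  "neutral",   "neutral")
  ))
}

#' Generate the full synthetic maturation study
#'
#' Emits the lineage plus replicate titrations and melts for every
#' construct in [pseries_truths()], with the generating truths as a
#' sidecar. All constructs share one concentration ladder (10 half-log
#' steps, 1e-9 to 3.16e-5 M) so weak binders fall off the measurable
#' range exactly as in the qualitative study pattern.
#'
#' @param seed Master integer seed; every construct/replicate draws from
#'   a substream of it.
#' @param dir Optional output directory; when given, writes
#'   `lineage.json`, `titrations.csv`, `melts.csv` and `truths.json`.
#' @param titration_noise_sd Titration signal noise (a.u.).
#' @param melt_noise_sd Melt signal noise (mdeg).
#' @param n_affinity_reps,n_melt_reps Replicates per construct.
#' @return List: `lineage`, `titrations` (`[[construct]]` list of data
#'   frames), `melts` (`[[construct]]` list of first/second scans),
#'   `truths` (the sidecar data frame).
#' @export
gen_pseries_bundle <- function(seed = 1L, dir = NULL,
                               titration_noise_sd = 40,
                               melt_noise_sd = 0.3,
                               n_affinity_reps = 4L,
                               n_melt_reps = 2L) {
  truths <- pseries_truths()
  lineage <- synthetic_vh_lineage()
  ladder <- 1e-9 * 10^seq(0, 4.5, by = 0.5)
  titrations <- list()
  melts <- list()
  for (i in seq_len(nrow(truths))) {
    construct <- truths$construct[i]
    tt <- titration_truth(kd = truths$kd_true[i],
                          concentrations = ladder,
                          noise_sd = titration_noise_sd,
                          n_replicates = n_affinity_reps,
                          seed = stream_seed(seed, 1L, i))
    titrations[[construct]] <- gen_titration(tt)
    mt <- melt_truth(tm = truths$tm_true[i],
                     noise_sd = melt_noise_sd,
                     reversibility = 0.9,
                     n_replicates = n_melt_reps,
                     seed = stream_seed(seed, 2L, i))
    melts[[construct]] <- gen_melt(mt)
  }
  bundle <- list(lineage = lineage, titrations = titrations, melts = melts,
                 truths = truths)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_lineage(lineage, file.path(dir, "lineage.json"))
    tit_df <- do.call(rbind, lapply(names(titrations), function(v) {
      do.call(rbind, lapply(seq_along(titrations[[v]]), function(r) {
        data.frame(variant = v, replicate = r,
                   conc_M = titrations[[v]][[r]]$conc,
                   signal = titrations[[v]][[r]]$signal)
      }))
    }))
    utils::write.csv(tit_df, file.path(dir, "titrations.csv"),
                     row.names = FALSE)
    melt_df <- do.call(rbind, lapply(names(melts), function(v) {
      do.call(rbind, lapply(seq_along(melts[[v]]), function(r) {
        rep_ <- melts[[v]][[r]]
        rbind(data.frame(variant = v, scan = 1, replicate = r,
                         temp_C = rep_$first$temp, signal = rep_$first$signal),
              if (!is.null(rep_$second)) {
                data.frame(variant = v, scan = 2, replicate = r,
                           temp_C = rep_$second$temp,
                           signal = rep_$second$signal)
              })
      }))
    }))
    utils::write.csv(melt_df, file.path(dir, "melts.csv"), row.names = FALSE)
    jsonlite::write_json(truths, file.path(dir, "truths.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  }
  bundle
}

#' Run the full trade-off pipeline on a bundle
#'
#' Fits every titration and melt of a [gen_pseries_bundle()] (or data
#' read back from its CSV outputs) and assembles the trade-off table.
#'
#' @param bundle List with `titrations`, `melts`, `lineage`.
#' @param binding_cfg,melt_cfg Module settings.
#' @param test_variant Passed to [students_t_test()].
#' @return List: `affinity` summaries, `stability` summaries, `tradeoff`
#'   table.
#' @export
run_pseries_pipeline <- function(bundle,
                                 binding_cfg = binding_config(),
                                 melt_cfg = melt_config(),
                                 test_variant = "equal") {
  affinity <- fit_all_titrations(bundle$titrations, binding_cfg)
  stability <- fit_all_melts(bundle$melts, melt_cfg)
  tradeoff <- build_tradeoff_table(affinity, stability, bundle$lineage,
                                   test_variant = test_variant)
  list(affinity = affinity, stability = stability, tradeoff = tradeoff)
}
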