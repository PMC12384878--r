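# Synthetic cohort generator: traits, behavior trials, connectomes, imaging
# metrics and expression counts with planted, parameterized structure, so that
# each downstream stage has a ground-truth recovery test.

#' The eight a priori olfactory-memory regions used for imaging coupling
#'
#' Regions of the olfactory-memory circuit selected for focused
#' eigengene-imaging analysis.
#' @export
olf_regions <- c(
  "Piriform Cortex", "Amygdalopiriform Transition Area",
  "Posterolateral Cortical Amygdaloid Area", "Perirhinal Cortex",
  "Hippocampus", "Postsubiculum", "Parasubiculum", "Ventral Orbital Cortex"
)

#' Default imaging metric panel
#'
#' Diffusion-tensor metrics (AD, RD, MD, FA), mean-apparent-propagator
#' metrics (MSD, QIV, RTOP) and relative regional volume.
#' @export
olf_metrics <- c("AD", "RD", "MD", "FA", "MSD", "QIV", "RTOP", "volume_pct")

# Metrics entering the 8 x 10 x 7 coupling grid (volume excluded).
#' Coupling-grid metric panel (7 diffusion/propagator metrics)
#' @export
coupling_metrics <- c("AD", "RD", "MD", "FA", "MSD", "QIV", "RTOP")

#' Construct a simulation specification
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size and
#' allocation, planted factorial effects on the recognition index, the shared
#' cross-domain latent factor, the planted eigengene-imaging correlation, the
#' blood-brain module correlation, and noise scales. All generators are pure
#' functions of `(spec, seed)`; per-table child seeds are derived from
#' `seed` by fixed offsets.
#'
#' @param n_subjects cohort size (ignored when `cell_counts` is given).
#' @param cell_counts optional allocation preset, as returned by
#'   [table1_cell_counts()]; a data frame with one row per APOE x diet cell
#'   and marginal counts for sex, age group and NOS2 background.
#' @param effect_sizes named list of planted shifts on the recognition index
#'   (probability scale): `ri_apoe4`, `ri_hfd`, `ri_18mo` main-effect shifts
#'   and `ri_apoe4_hfd_18mo` for the three-way cell.
#' @param latent_edge_loading correlation loading between each designated
#'   connectome edge and the shared latent factor.
#' @param n_latent_edges number of designated edges carrying the latent
#'   factor.
#' @param latent_behavior_loading loading of the latent factor on behavioral
#'   engagement (added to investigation times on a standardized scale).
#' @param latent_trait_loading correlation between the latent factor and the
#'   composite risk contrast built from APOE4/HFD/age.
#' @param eigengene_metric_r planted correlation between the designated
#'   expression module score and the designated (region, metric) imaging
#'   cells; must lie in (-1, 1).
#' @param coupling_module index of the expression module carrying the
#'   imaging coupling (default 2, mirroring the dominant blood module).
#' @param blood_brain_r correlation between blood and brain module scores.
#' @param habituation_decay multiplicative decay of investigation per trial
#'   across habituation trials 1-4.
#' @param dishabituation_gain multiplicative bump on the odor-switched
#'   object at trial 5, relative to its trial-4 mean.
#' @param noise_sd residual SD (seconds) of investigation times.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param n_genes,n_modules,module_size expression-matrix dimensions.
#' @param n_regions connectome parcellation size (default 332 labels).
#' @param n_imaging,n_expression subset sizes used by
#'   [write_fixture_bundle()] for the imaging and expression cohorts.
#' @param seed master seed.
#' @return an object of class `olfnet_spec`.
#' @export
simulation_spec <- function(n_subjects = 465L,
                            cell_counts = NULL,
                            effect_sizes = list(ri_apoe4 = -0.03,
                                                ri_hfd = -0.02,
                                                ri_18mo = -0.04,
                                                ri_apoe4_hfd_18mo = -0.06),
                            latent_edge_loading = 0.45,
                            n_latent_edges = 20L,
                            latent_behavior_loading = 0.5,
                            latent_trait_loading = 0.4,
                            eigengene_metric_r = -0.5,
                            coupling_module = 2L,
                            blood_brain_r = 0.7,
                            habituation_decay = 0.8,
                            dishabituation_gain = 1.8,
                            noise_sd = 1,
                            nb_dispersion = 0.3,
                            n_genes = 1000L,
                            n_modules = 10L,
                            module_size = 40L,
                            n_regions = 332L,
                            n_imaging = 175L,
                            n_expression = 130L,
                            seed = 1L) {
  if (!is.null(cell_counts)) {
    n_subjects <- sum(cell_counts$total)
  }
  if (n_subjects < 1) stop_config("n_subjects must be positive")
  if (abs(eigengene_metric_r) >= 1)
    stop_config("|eigengene_metric_r| must be < 1")
  if (noise_sd <= 0) stop_config("noise_sd must be > 0")
  if (n_modules * module_size > n_genes)
    stop_config("module genes exceed n_genes")
  spec <- list(
    n_subjects = as.integer(n_subjects), cell_counts = cell_counts,
    effect_sizes = effect_sizes,
    latent_edge_loading = latent_edge_loading,
    n_latent_edges = as.integer(n_latent_edges),
    latent_behavior_loading = latent_behavior_loading,
    latent_trait_loading = latent_trait_loading,
    eigengene_metric_r = eigengene_metric_r,
    coupling_module = as.integer(coupling_module),
    blood_brain_r = blood_brain_r,
    habituation_decay = habituation_decay,
    dishabituation_gain = dishabituation_gain,
    noise_sd = noise_sd, nb_dispersion = nb_dispersion,
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    n_regions = as.integer(n_regions),
    n_imaging = as.integer(n_imaging),
    n_expression = as.integer(n_expression),
    seed = as.integer(seed))
  class(spec) <- "olfnet_spec"
  spec
}

#' Cohort allocation preset matching the published behavioral cohort table
#'
#' One row per APOE genotype x diet cell with the cell total and the
#' marginal counts of sex, age group and NOS2 background within the cell.
#' Totals 465 subjects.
#' @return data frame with columns `apoe`, `diet`, `female`, `male`,
#'   `mo18`, `mo12`, `mnos2`, `hn`, `total`.
#' @export
table1_cell_counts <- function() {
  data.frame(
    apoe  = rep(c("APOE2", "APOE3", "APOE4"), each = 2),
    diet  = rep(c("control", "hfd"), 3),
    female = c(46, 37, 45, 35, 41, 39),
    male   = c(48, 34, 41, 33, 35, 31),
    mo18   = c(51, 31, 41, 32, 28, 23),
    mo12   = c(43, 40, 45, 36, 48, 47),
    mnos2  = c(48, 29, 43, 30, 43, 34),
    hn     = c(46, 42, 43, 38, 33, 36),
    total  = c(94, 71, 86, 68, 76, 70),
    stringsAsFactors = FALSE)
}

trait_levels <- list(
  apoe = c("APOE2", "APOE3", "APOE4"),
  diet = c("control", "hfd"),
  sex = c("F", "M"),
  age_group = c("12", "18"),
  nos2 = c("mNOS2", "HN"))

#' Generate the cohort trait table
#'
#' When `spec$cell_counts` is given (e.g. [table1_cell_counts()]), each
#' APOE x diet cell receives exactly its stated total, and the sex, age and
#' NOS2 columns are filled so that every within-cell marginal count is
#' reproduced exactly; the joint distribution beyond those marginals is a
#' seeded random coupling. Without `cell_counts`, subjects are allocated by
#' proportional multinomial sampling over all factor combinations.
#'
#' @param spec an [simulation_spec()] object.
#' @return data frame with columns `subject_id`, `apoe`, `diet`, `sex`,
#'   `age_group`, `nos2`; one row per subject.
#' @export
generate_traits <- function(spec) {
  stopifnot(inherits(spec, "olfnet_spec"))
  with_child_seed(spec$seed, 1L, {
    if (!is.null(spec$cell_counts)) {
      cc <- spec$cell_counts
      need <- c("apoe", "diet", "female", "male", "mo18", "mo12",
                "mnos2", "hn", "total")
      if (!all(need %in% names(cc)))
        stop_config("cell_counts is missing columns: ",
                    paste(setdiff(need, names(cc)), collapse = ", "))
      bad <- with(cc, female + male != total | mo18 + mo12 != total |
                    mnos2 + hn != total)
      if (any(bad))
        stop_config("cell_counts marginals do not sum to cell totals in ",
                    sum(bad), " cell(s)")
      rows <- lapply(seq_len(nrow(cc)), function(k) {
        n <- cc$total[k]
        data.frame(
          apoe = cc$apoe[k], diet = cc$diet[k],
          sex = sample(rep(c("F", "M"), c(cc$female[k], cc$male[k]))),
          age_group = sample(rep(c("18", "12"), c(cc$mo18[k], cc$mo12[k]))),
          nos2 = sample(rep(c("mNOS2", "HN"), c(cc$mnos2[k], cc$hn[k]))),
          stringsAsFactors = FALSE)
      })
      traits <- do.call(rbind, rows)
    } else {
      grid <- expand.grid(trait_levels, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      idx <- sample.int(nrow(grid), spec$n_subjects, replace = TRUE)
      traits <- grid[idx, , drop = FALSE]
    }
    traits <- traits[, c("apoe", "diet", "sex", "age_group", "nos2")]
    rownames(traits) <- NULL
    n <- nrow(traits)
    traits <- cbind(subject_id = sprintf("S%04d", seq_len(n)), traits,
                    stringsAsFactors = FALSE)
    for (nm in names(trait_levels))
      traits[[nm]] <- factor(traits[[nm]], levels = trait_levels[[nm]])
    traits
  })
}

subject_index <- function(subject_id) as.integer(sub("^S", "", subject_id))

# Shared latent factor: one standard-normal score per subject, partially
# determined by the composite risk contrast so the trait domain couples to
# it. Noise draws are keyed by subject index so nested sub-cohorts (imaging,
# blood, brain tissue) see the same per-subject scores.
latent_scores <- function(traits, spec) {
  noise <- with_child_seed(spec$seed, 2L, rnorm(spec$n_subjects))
  risk <- (traits$apoe == "APOE4") - (traits$apoe == "APOE2") +
    (traits$diet == "hfd") + (traits$age_group == "18")
  risk <- as.numeric(scale(risk))
  if (any(is.na(risk))) risk <- rep(0, nrow(traits))
  l <- spec$latent_trait_loading
  z <- l * risk + sqrt(1 - l^2) * noise[subject_index(traits$subject_id)]
  setNames(as.numeric(scale(z)), traits$subject_id)
}

# Expression module scores on the blood side; brain tissues receive
# correlated copies at blood_brain_r (see generate_expression). Keyed by
# subject index for sub-cohort consistency.
module_scores <- function(traits, spec) {
  full <- with_child_seed(spec$seed, 7L,
                          matrix(rnorm(spec$n_subjects * spec$n_modules),
                                 spec$n_subjects))
  m <- scale(full[subject_index(traits$subject_id), , drop = FALSE])
  dimnames(m) <- list(traits$subject_id,
                      paste0("module", seq_len(spec$n_modules)))
  m
}

ri_shift <- function(traits, es) {
  sh <- rep(0, nrow(traits))
  sh <- sh + (traits$apoe == "APOE4") * (es$ri_apoe4 %||% 0)
  sh <- sh + (traits$diet == "hfd") * (es$ri_hfd %||% 0)
  sh <- sh + (traits$age_group == "18") * (es$ri_18mo %||% 0)
  sh <- sh + (traits$apoe == "APOE4" & traits$diet == "hfd" &
                traits$age_group == "18") * (es$ri_apoe4_hfd_18mo %||% 0)
  sh
}

#' Generate behavioral trial tables
#'
#' Emits, per subject: four odor-preference trials with four objects at
#' concentrations 0, 0.001, 0.01 and 0.1 v/v; a five-trial
#' habituation/dishabituation series with multiplicative decay across trials
#' 1-4 and a novelty bump on the odor-switched object at trial 5; and three
#' recognition-memory probes (1 h, 24 h, 48 h delays) with planted
#' genotype x diet x age shifts on the expected recognition index. All
#' investigation times are nonnegative and per-trial tracked time is at
#' least the summed object time.
#'
#' @param traits trait table from [generate_traits()].
#' @param spec the matching [simulation_spec()].
#' @return long data frame: `subject`, `task`, `trial`, `object`, `odor`,
#'   `concentration`, `delay_h`, `investigation_s`, `tracked_s`.
#' @export
generate_behavior <- function(traits, spec) {
  if (nrow(traits) == 0) stop_data("traits table is empty")
  z <- latent_scores(traits, spec)
  es <- spec$effect_sizes
  with_child_seed(spec$seed, 3L, {
    n <- nrow(traits)
    concs <- c(0, 0.001, 0.01, 0.1)
    rows <- vector("list", n)
    for (s in seq_len(n)) {
      id <- traits$subject_id[s]
      lz <- spec$latent_behavior_loading * z[[id]]
      # Odor preference: salience grows with concentration rank.
      pref <- expand.grid(trial = 1:4, object = 1:4)
      mu_p <- 3 + 1.6 * (pref$object - 1) + lz
      pref_inv <- rnorm_pos(nrow(pref), mu_p, spec$noise_sd)
      pref_df <- data.frame(
        subject = id, task = "preference", trial = pref$trial,
        object = pref$object, odor = "lemon",
        concentration = concs[pref$object], delay_h = NA_real_,
        investigation_s = pref_inv, stringsAsFactors = FALSE)
      # Habituation (trials 1-4) and dishabituation (trial 5, object 1).
      hab <- expand.grid(trial = 1:5, object = 1:4)
      base <- 8 + lz
      mu_h <- base * spec$habituation_decay^(hab$trial - 1)
      novel <- hab$trial == 5 & hab$object == 1
      mu_h[novel] <- base * spec$habituation_decay^3 *
        spec$dishabituation_gain
      hab_inv <- rnorm_pos(nrow(hab), mu_h, spec$noise_sd)
      hab_df <- data.frame(
        subject = id, task = "habdis", trial = hab$trial,
        object = hab$object,
        odor = ifelse(novel, "vanilla", "lemon"),
        concentration = 0.01, delay_h = NA_real_,
        investigation_s = hab_inv, stringsAsFactors = FALSE)
      # Memory probes: novel vs familiar object at three delays.
      delays <- c(1, 24, 48)
      novel_odors <- c("almond", "anise", "banana")
      p_novel <- pmin(pmax(0.62 + ri_shift(traits[s, , drop = FALSE], es) -
                             0.015 * (seq_along(delays) - 1), 0.05), 0.95)
      tot <- rnorm_pos(3, 10 + lz, 2)
      no <- rnorm_pos(3, tot * p_novel, spec$noise_sd)
      fo <- rnorm_pos(3, tot * (1 - p_novel), spec$noise_sd)
      mem_df <- data.frame(
        subject = id, task = "memory",
        trial = rep(seq_along(delays), each = 2),
        object = rep(1:2, 3),
        odor = as.vector(rbind(novel_odors, "coconut")),
        concentration = NA_real_,
        delay_h = rep(delays, each = 2),
        investigation_s = as.vector(rbind(no, fo)),
        stringsAsFactors = FALSE)
      rows[[s]] <- rbind(pref_df, hab_df, mem_df)
    }
    out <- do.call(rbind, rows)
    # Tracked time per trial: 120 s arena trials, 60 s memory probes; never
    # below the summed investigation time.
    key <- paste(out$subject, out$task, out$trial)
    tot_by_trial <- tapply(out$investigation_s, key, sum)[key]
    base_tracked <- ifelse(out$task == "memory", 60, 120)
    out$tracked_s <- pmax(base_tracked, tot_by_trial)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic structural connectomes
#'
#' Symmetric nonnegative integer streamline-count matrices over a shared
#' region label set. A designated set of edges carries the shared latent
#' factor: on the standardized scale the edge value is
#' `loading * z + sqrt(1 - loading^2) * noise`, mapped onto a count scale.
#'
#' @param traits trait table.
#' @param spec the matching spec; `spec$n_regions` labels are generated as
#'   `R001..` unless `region_labels` is supplied.
#' @param region_labels optional character vector of region names.
#' @return named list (by subject) of square labeled integer matrices.
#' @export
generate_connectomes <- function(traits, spec, region_labels = NULL) {
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(spec$n_regions))
  p <- length(region_labels)
  if (p < 3) stop_data("need at least 3 regions")
  z <- latent_scores(traits, spec)
  with_child_seed(spec$seed, 4L, {
    pairs <- upper_tri_pairs(p)
    n_edges <- nrow(pairs)
    # Subject-invariant baseline intensity per edge (sparse-ish, heavy tail).
    lam <- rgamma(n_edges, shape = 0.6, rate = 0.04)
    k <- min(spec$n_latent_edges, n_edges)
    latent_edges <- seq_len(k)
    l <- spec$latent_edge_loading
    n <- nrow(traits)
    eps <- matrix(rnorm(n * k), n, k)
    out <- vector("list", n)
    for (s in seq_len(n)) {
      counts <- rpois(n_edges, lam)
      if (k > 0 && l != 0) {
        std <- l * z[[s]] + sqrt(1 - l^2) * eps[s, ]
        mu <- lam[latent_edges] + 20
        counts[latent_edges] <- pmax(0L, as.integer(round(
          mu + sqrt(mu) * 1.5 * std)))
      }
      m <- matrix(0L, p, p, dimnames = list(region_labels, region_labels))
      m[pairs] <- counts
      m <- m + t(m)
      out[[s]] <- m
    }
    names(out) <- traits$subject_id
    out
  })
}

#' Generate regional imaging metric tables
#'
#' Per subject x region x metric values on plausible scales (FA clipped to
#' \[0, 1\]). Designated (region, metric) cells correlate with the designated
#' expression module score at `spec$eigengene_metric_r`.
#'
#' @param traits trait table.
#' @param spec the matching spec.
#' @param regions region name vector (default the 8 a priori regions).
#' @param metrics metric name vector (default [olf_metrics]).
#' @param coupled_cells data frame with columns `region`, `metric` naming
#'   the cells that carry the planted module correlation; defaults to the
#'   diffusivity cells of the subicular-hippocampal axis.
#' @return long data frame: `subject`, `region`, `metric`, `value`.
#' @export
generate_imaging_metrics <- function(traits, spec,
                                     regions = olf_regions,
                                     metrics = olf_metrics,
                                     coupled_cells = NULL) {
  known <- list(AD = c(0.9e-3, 1e-4), RD = c(0.5e-3, 7e-5),
                MD = c(0.7e-3, 8e-5), FA = c(0.35, 0.05),
                MSD = c(1.5e-4, 2e-5), QIV = c(0.5, 0.08),
                RTOP = c(8e4, 1e4), NG = c(0.4, 0.06),
                RTAP = c(2e3, 250), RTPP = c(45, 6),
                volume_pct = c(0.4, 0.07))
  bad <- setdiff(metrics, names(known))
  if (length(bad))
    stop_data("unknown metric name(s): ", paste(bad, collapse = ", "))
  if (is.null(coupled_cells)) {
    coupled_cells <- data.frame(
      region = c("Parasubiculum", "Parasubiculum", "Parasubiculum",
                 "Hippocampus", "Postsubiculum"),
      metric = c("AD", "MD", "RD", "AD", "AD"),
      stringsAsFactors = FALSE)
    coupled_cells <- coupled_cells[coupled_cells$region %in% regions &
                                     coupled_cells$metric %in% metrics, ]
  }
  mscore <- module_scores(traits, spec)[, spec$coupling_module]
  r <- spec$eigengene_metric_r
  with_child_seed(spec$seed, 5L, {
    grid <- expand.grid(region = regions, metric = metrics,
                        stringsAsFactors = FALSE)
    n <- nrow(traits)
    rows <- lapply(seq_len(nrow(grid)), function(g) {
      mm <- known[[grid$metric[g]]]
      coupled <- any(coupled_cells$region == grid$region[g] &
                       coupled_cells$metric == grid$metric[g])
      std <- if (coupled) {
        r * mscore + sqrt(1 - r^2) * rnorm(n)
      } else {
        rnorm(n)
      }
      val <- mm[1] + mm[2] * std
      if (grid$metric[g] == "FA") val <- pmin(pmax(val, 0), 1)
      if (grid$metric[g] == "volume_pct") val <- pmax(val, 0)
      data.frame(subject = traits$subject_id, region = grid$region[g],
                 metric = grid$metric[g], value = val,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate expression count matrices per tissue
#'
#' Nonnegative negative-binomial count matrices (genes x subjects) with
#' block module structure: the first `n_modules * module_size` genes load in
#' blocks on per-subject module scores. Brain tissues receive module scores
#' correlated with the blood scores at `spec$blood_brain_r`, so blood-brain
#' PC coupling is recoverable. Library sizes are log-normal (CV 20%), so
#' normalization matters.
#'
#' @param traits trait table (brain tissues may use a subset; pass the
#'   subset's traits).
#' @param spec the matching spec.
#' @param tissues character vector of tissue names; `"blood"` uses the base
#'   module scores, all other names get correlated copies.
#' @return named list of integer matrices, genes x subjects, with gene
#'   symbols as rownames and subject ids as colnames.
#' @export
generate_expression <- function(traits, spec,
                                tissues = c("blood", "hippocampus",
                                            "hypothalamus", "frontal_cortex",
                                            "cingulate_cortex")) {
  if (length(tissues) == 0) stop_data("tissues must be non-empty")
  if (spec$n_genes < 50) stop_data("need at least 50 genes")
  base_scores <- module_scores(traits, spec)
  n <- nrow(traits)
  genes <- sprintf("Gene%04d", seq_len(spec$n_genes))
  module_of <- rep(NA_integer_, spec$n_genes)
  for (m in seq_len(spec$n_modules)) {
    module_of[((m - 1) * spec$module_size + 1):(m * spec$module_size)] <- m
  }
  # Module strength decays geometrically so successive eigenvalues stay
  # well separated and PC order tracks module order.
  strength <- 1.8 * 0.88^(seq_len(spec$n_modules) - 1)
  out <- list()
  for (ti in seq_along(tissues)) {
    tissue <- tissues[ti]
    out[[tissue]] <- with_child_seed(spec$seed, 10L + ti, {
      scores <- if (identical(tissue, "blood")) {
        base_scores
      } else {
        rho <- spec$blood_brain_r
        scale(rho * base_scores +
              sqrt(1 - rho^2) * matrix(rnorm(n * spec$n_modules), n))
      }
      # Module genes are a small share of the library (moderate baseline)
      # and a block of stable high-expression housekeeping genes anchors
      # it, keeping CPM compositional coupling between modules negligible.
      log_base <- log(200) + rnorm(spec$n_genes, 0, 1)
      log_base[!is.na(module_of)] <-
        log(50) + rnorm(sum(!is.na(module_of)), 0, 0.4)
      hk <- is.na(module_of) &
        seq_len(spec$n_genes) > spec$n_genes - max(50L, spec$n_genes %/% 20L)
      log_base[hk] <- log(4000) + rnorm(sum(hk), 0, 0.3)
      loading <- ifelse(is.na(module_of), 0,
                        runif(spec$n_genes, 0.5, 0.9) * strength[
                          ifelse(is.na(module_of), 1L, module_of)])
      eta <- matrix(log_base, spec$n_genes, n)
      for (m in seq_len(spec$n_modules)) {
        in_m <- which(module_of == m)
        eta[in_m, ] <- eta[in_m, ] +
          outer(loading[in_m], scores[, m])
      }
      libsize <- exp(rnorm(n, 0, sqrt(log(1 + 0.2^2))))
      mu <- sweep(exp(eta), 2, libsize, `*`)
      counts <- matrix(rnbinom(length(mu), mu = mu,
                               size = 1 / spec$nb_dispersion),
                       spec$n_genes, n)
      dimnames(counts) <- list(genes, traits$subject_id)
      counts
    })
  }
  out
}

#' Write a complete synthetic fixture bundle
#'
#' Writes traits, behavior trials, connectomes, imaging metrics and
#' expression matrices in their on-disk dialects plus a JSON manifest of
#' parameters, seeds and file checksums. Imaging/connectome tables cover the
#' first `spec$n_imaging` subjects and expression the first
#' `spec$n_expression` (brain tissues the first 32), mirroring the nested
#' cohort design. Re-running with the same spec reproduces every file
#' byte-identically.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [simulation_spec()].
#' @param tissues tissue names passed to [generate_expression()].
#' @param n_brain_tissue number of subjects per brain tissue.
#' @return the manifest, invisibly.
#' @export
write_fixture_bundle <- function(out_dir, spec,
                                 tissues = c("blood", "hippocampus",
                                             "hypothalamus", "frontal_cortex",
                                             "cingulate_cortex"),
                                 n_brain_tissue = 32L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traits <- generate_traits(spec)
  behavior <- generate_behavior(traits, spec)
  img_traits <- traits[seq_len(min(spec$n_imaging, nrow(traits))), ]
  expr_traits <- traits[seq_len(min(spec$n_expression, nrow(traits))), ]
  conns <- generate_connectomes(img_traits, spec)
  imaging <- generate_imaging_metrics(img_traits, spec)
  expr <- list()
  for (tissue in tissues) {
    tt <- if (identical(tissue, "blood")) expr_traits else
      expr_traits[seq_len(min(n_brain_tissue, nrow(expr_traits))), ]
    expr[[tissue]] <- generate_expression(tt, spec, tissues = tissue)[[1]]
  }
  files <- character(0)
  wf <- function(name) {
    path <- file.path(out_dir, name)
    files <<- c(files, path)
    path
  }
  write.csv(traits, wf("traits.csv"), row.names = FALSE)
  write.csv(behavior, wf("behavior_trials.csv"), row.names = FALSE)
  for (id in names(conns)) {
    write.table(conns[[id]], wf(sprintf("connectome_%s.tsv", id)),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  write.csv(imaging, wf("imaging.csv"), row.names = FALSE)
  for (tissue in names(expr)) {
    df <- data.frame(gene = rownames(expr[[tissue]]), expr[[tissue]],
                     check.names = FALSE)
    write.table(df, wf(sprintf("expr_%s.tsv", tissue)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    spec = unclass(spec)[setdiff(names(spec), "cell_counts")],
    cell_counts_preset = !is.null(spec$cell_counts),
    child_seeds = list(traits = child_seed(spec$seed, 1L),
                       latent = child_seed(spec$seed, 2L),
                       behavior = child_seed(spec$seed, 3L),
                       connectome = child_seed(spec$seed, 4L),
                       imaging = child_seed(spec$seed, 5L),
                       modules = child_seed(spec$seed, 7L)),
    files = lapply(seq_along(files), function(i) {
      list(path = basename(files[i]),
           md5 = unname(tools::md5sum(files[i])))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a connectome TSV written by [write_fixture_bundle()]
#' @param path file path.
#' @return labeled integer matrix.
#' @export
read_connectome <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  m
}

#' Read an expression TSV (genes x subjects, first column gene symbols)
#' @param path file path.
#' @return integer matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
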