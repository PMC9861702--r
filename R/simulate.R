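# Synthetic cohort generator. Emulates the statistical structure of the
# combination-screen data the model assumes: drug and cell-line feature
# vectors that are noisy linear images of low-dimensional latent embeddings;
# per-(pair, cell line) synergy scores that are symmetric under drug swap
# and positively cross-correlated through a shared latent component;
# pair-level (cell-line-independent) adverse-DDI labels; strong class
# imbalance for the synergy label; and optional replicate measurements.

#' Simulation configuration
#'
#' Default dimensions are reduced (p_d = 64, p_c = 32, latent_dim = 8) so
#' that tests run in seconds; full-scale dimensions (541/927) are available
#' as options. Each synergy task t is generated as
#' \deqn{score_t = scale (shared_w_t f + specific_w_t g_t) + N(0, noise_sd_t)}
#' where f and the g_t are symmetric functions of the drug latent embeddings
#' (built from elementwise products and sums) and of the cell-line embedding.
#' The shared component f induces positive cross-task correlation controlled
#' by \code{task_shared_weight}. The Loewe intercept is calibrated so that
#' the fraction of samples above the synergy threshold matches
#' \code{target_positive_rate} (default 1/16, i.e. a 1:15 class imbalance).
#' The S-score analog gets a small shared weight by default, reproducing its
#' weak correlation with the other scores.
#'
#' @param n_drugs,n_cells numbers of drugs and cell lines.
#' @param p_d,p_c feature dimensions.
#' @param n_samples number of (pair, cell line) samples.
#' @param latent_dim latent embedding dimension.
#' @param task_shared_weight,task_specific_weight named per-task weights of
#'   the shared and task-specific score components.
#' @param noise_sd named per-task measurement-noise standard deviations.
#' @param score_scale overall scale of the systematic score component.
#' @param feature_noise_sd observation noise on the feature tables.
#' @param synergy_threshold synergy-label threshold.
#' @param target_positive_rate desired synergy-positive fraction.
#' @param ddi_positive_rate fraction of drug pairs with an adverse DDI.
#' @param replicate_prob probability that a sample is emitted twice with
#'   independent noise (default 0: the post-averaging cohort).
#' @param seed master seed; entity generation, score noise and sampling use
#'   independent sub-streams derived from it.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_drugs = 60L, n_cells = 8L, p_d = 64L, p_c = 32L,
                       n_samples = 4000L, latent_dim = 8L,
                       task_shared_weight = c(loewe = 1, bliss = 1, zip = 1,
                                              hsa = 1, s = 0.35),
                       task_specific_weight = c(loewe = 0.6, bliss = 0.5,
                                                zip = 0.5, hsa = 0.4, s = 1),
                       noise_sd = c(loewe = 3, bliss = 3, zip = 3, hsa = 3, s = 3),
                       score_scale = 10,
                       feature_noise_sd = 0.05,
                       synergy_threshold = 5,
                       target_positive_rate = 1 / 16,
                       ddi_positive_rate = 0.07,
                       replicate_prob = 0,
                       seed = 1L) {
  stopifnot(n_drugs >= 2, n_cells >= 1, p_d >= 1, p_c >= 1, n_samples >= 1,
            latent_dim >= 1,
            target_positive_rate > 0, target_positive_rate < 1,
            ddi_positive_rate > 0, ddi_positive_rate < 1,
            replicate_prob >= 0, replicate_prob <= 1)
  for (v in c("task_shared_weight", "task_specific_weight", "noise_sd")) {
    x <- get(v)
    if (!all(REGRESSION_TASKS %in% names(x)))
      stop(sprintf("%s must be named with all of: %s", v,
                   paste(REGRESSION_TASKS, collapse = ", ")))
  }
  structure(list(n_drugs = as.integer(n_drugs), n_cells = as.integer(n_cells),
                 p_d = as.integer(p_d), p_c = as.integer(p_c),
                 n_samples = as.integer(n_samples),
                 latent_dim = as.integer(latent_dim),
                 task_shared_weight = task_shared_weight[REGRESSION_TASKS],
                 task_specific_weight = task_specific_weight[REGRESSION_TASKS],
                 noise_sd = noise_sd[REGRESSION_TASKS],
                 score_scale = score_scale,
                 feature_noise_sd = feature_noise_sd,
                 synergy_threshold = synergy_threshold,
                 target_positive_rate = target_positive_rate,
                 ddi_positive_rate = ddi_positive_rate,
                 replicate_prob = replicate_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic 31-bit string hash, used to derive independent sub-streams
str_hash <- function(..., seed = 0L) {
  s <- paste(c(...), collapse = "\r")
  h <- as.numeric(seed) %% 2147483647
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

sym_weights <- function(L) {
  list(u = rnorm(L, sd = 1 / sqrt(L)), v = rnorm(L, sd = 1 / sqrt(L)),
       xc = rnorm(L, sd = 1 / sqrt(L)), c = rnorm(L, sd = 1 / sqrt(L)))
}

# symmetric score component: Ex, Ey, Ec are n x L latent matrices
sym_component <- function(Ex, Ey, Ec, w) {
  u <- Ex * Ey
  v <- Ex + Ey
  drop(u %*% w$u + v %*% w$v + (v * Ec) %*% w$xc + Ec %*% w$c)
}

#' Generate latent entities, feature tables and ground truth
#'
#' Drug features are a noisy linear image of an i.i.d. standard-normal latent
#' embedding (and likewise for cell lines). The ground truth also carries the
#' parameters of the score-generating functions and the adverse-DDI pair set
#' (an unordered-pair property, independent of cell line).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{store} (a \code{\link{feature_store}}) and
#'   \code{truth}.
#' @export
generate_entities <- function(config) {
  L <- config$latent_dim
  with_seed(str_hash("entities", seed = config$seed), {
    drug_ids <- sprintf("drug%03d", seq_len(config$n_drugs))
    cell_ids <- sprintf("cell%02d", seq_len(config$n_cells))
    Zd <- matrix(rnorm(config$n_drugs * L), config$n_drugs, L,
                 dimnames = list(drug_ids, NULL))
    Ad <- matrix(rnorm(L * config$p_d, sd = 1 / sqrt(L)), L, config$p_d)
    drug_feat <- Zd %*% Ad + matrix(rnorm(config$n_drugs * config$p_d,
                                          sd = config$feature_noise_sd),
                                    config$n_drugs, config$p_d)
    colnames(drug_feat) <- sprintf("desc%03d", seq_len(config$p_d))
    Zc <- matrix(rnorm(config$n_cells * L), config$n_cells, L,
                 dimnames = list(cell_ids, NULL))
    Ac <- matrix(rnorm(L * config$p_c, sd = 1 / sqrt(L)), L, config$p_c)
    cell_feat <- Zc %*% Ac + matrix(rnorm(config$n_cells * config$p_c,
                                          sd = config$feature_noise_sd),
                                    config$n_cells, config$p_c)
    colnames(cell_feat) <- sprintf("gene%03d", seq_len(config$p_c))
    shared_w <- sym_weights(L)
    task_w <- stats::setNames(lapply(REGRESSION_TASKS, function(t) sym_weights(L)),
                              REGRESSION_TASKS)
    truth <- structure(list(
      drug_embeddings = Zd, cell_embeddings = Zc,
      shared_weights = shared_w, task_weights = task_w,
      loewe_shift = 0, ddi_pairs = character(0)), class = "deml_ground_truth")
    # pair-level adverse-DDI assignment, independent of cell line
    pairs <- utils::combn(drug_ids, 2)
    adverse <- logical(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      adverse[j] <- with_seed(str_hash("ddi", pairs[1, j], pairs[2, j],
                                       seed = config$seed),
                              runif(1)) < config$ddi_positive_rate
    }
    truth$ddi_pairs <- paste(pairs[1, adverse], pairs[2, adverse], sep = "\r")
    list(store = feature_store(drug_feat, cell_feat), truth = truth)
  })
}

# noise seeded by the unordered triple (+ replicate index), so regenerating
# a sample with swapped drugs reproduces its scores exactly
score_noise <- function(x, y, cell, replicate, config) {
  a <- pmin(x, y); b <- pmax(x, y)
  with_seed(str_hash("noise", a, b, cell, replicate, seed = config$seed),
            rnorm(length(REGRESSION_TASKS)) * config$noise_sd)
}

#' Generate the five synergy-score analogs for one combination
#'
#' Deterministic given the ground truth and configuration: the noise stream
#' is seeded by the unordered drug pair, the cell line and the replicate
#' index, so the scores are symmetric under swapping the two drugs.
#'
#' @param x,y drug ids.
#' @param cell cell-line id.
#' @param truth ground truth from \code{\link{generate_entities}}.
#' @param config the \code{\link{sim_config}}.
#' @param replicate replicate index (independent noise per replicate).
#' @return named numeric vector of the five scores.
#' @export
generate_task_targets <- function(x, y, cell, truth, config, replicate = 1L) {
  for (id in c(x, y)) {
    if (!id %in% rownames(truth$drug_embeddings)) stop("unknown drug id: ", id)
  }
  if (!cell %in% rownames(truth$cell_embeddings)) stop("unknown cell-line id: ", cell)
  Ex <- truth$drug_embeddings[x, , drop = FALSE]
  Ey <- truth$drug_embeddings[y, , drop = FALSE]
  Ec <- truth$cell_embeddings[cell, , drop = FALSE]
  f <- sym_component(Ex, Ey, Ec, truth$shared_weights)
  eps <- score_noise(x, y, cell, replicate, config)
  out <- numeric(length(REGRESSION_TASKS))
  names(out) <- REGRESSION_TASKS
  for (i in seq_along(REGRESSION_TASKS)) {
    t <- REGRESSION_TASKS[i]
    g <- sym_component(Ex, Ey, Ec, truth$task_weights[[t]])
    out[t] <- config$score_scale *
      (config$task_shared_weight[t] * f + config$task_specific_weight[t] * g) +
      eps[i]
  }
  out["loewe"] <- out["loewe"] + truth$loewe_shift
  out
}

#' Generate a full synthetic cohort
#'
#' Draws random (drug pair, cell line) triples, generates their synergy
#' scores, calibrates the Loewe-analog intercept so the synergy-positive
#' fraction matches the target rate, assigns pair-level DDI labels, and
#' optionally emits replicate measurements with independent noise (these can
#' be collapsed again with \code{\link{average_replicates}}). Byte-identical
#' output under the same configuration and seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{dataset} (a \code{\link{deml_dataset}}),
#'   \code{truth} (including the calibrated \code{loewe_shift}) and
#'   \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  ent <- generate_entities(config)
  truth <- ent$truth
  store <- ent$store
  drug_ids <- rownames(store$drug)
  cell_ids <- rownames(store$cell)
  n <- config$n_samples
  tri <- with_seed(str_hash("samples", seed = config$seed), {
    x <- sample(drug_ids, n, replace = TRUE)
    y <- sample(drug_ids, n, replace = TRUE)
    while (any(x == y)) {
      eq <- x == y
      y[eq] <- sample(drug_ids, sum(eq), replace = TRUE)
    }
    cl <- sample(cell_ids, n, replace = TRUE)
    rep_flag <- runif(n) < config$replicate_prob
    list(x = x, y = y, cl = cl, rep_flag = rep_flag)
  })
  # vectorized systematic component
  Ex <- truth$drug_embeddings[tri$x, , drop = FALSE]
  Ey <- truth$drug_embeddings[tri$y, , drop = FALSE]
  Ec <- truth$cell_embeddings[tri$cl, , drop = FALSE]
  f <- sym_component(Ex, Ey, Ec, truth$shared_weights)
  scores <- matrix(0, n, length(REGRESSION_TASKS),
                   dimnames = list(NULL, REGRESSION_TASKS))
  for (t in REGRESSION_TASKS) {
    g <- sym_component(Ex, Ey, Ec, truth$task_weights[[t]])
    scores[, t] <- config$score_scale *
      (config$task_shared_weight[t] * f + config$task_specific_weight[t] * g)
  }
  noise <- t(vapply(seq_len(n), function(i)
    score_noise(tri$x[i], tri$y[i], tri$cl[i], 1L, config),
    numeric(length(REGRESSION_TASKS))))
  scores <- scores + noise
  # calibrate the Loewe-analog intercept to the target positive rate
  shift <- config$synergy_threshold -
    stats::quantile(scores[, "loewe"], 1 - config$target_positive_rate,
                    names = FALSE)
  truth$loewe_shift <- shift
  scores[, "loewe"] <- scores[, "loewe"] + shift
  pair_key <- unordered_pair_key(tri$x, tri$y)
  samples <- data.frame(drug_x = tri$x, drug_y = tri$y, cell_line = tri$cl,
                        scores,
                        synergy_label = assign_synergy_label(
                          scores[, "loewe"], config$synergy_threshold),
                        ddi_label = as.integer(pair_key %in% truth$ddi_pairs),
                        stringsAsFactors = FALSE)
  if (any(tri$rep_flag)) {
    idx <- which(tri$rep_flag)
    rep2 <- samples[idx, , drop = FALSE]
    noise2 <- t(vapply(idx, function(i)
      score_noise(tri$x[i], tri$y[i], tri$cl[i], 2L, config),
      numeric(length(REGRESSION_TASKS))))
    for (j in seq_along(REGRESSION_TASKS)) {
      t <- REGRESSION_TASKS[j]
      rep2[[t]] <- rep2[[t]] - noise[idx, j] + noise2[, j]
    }
    rep2$synergy_label <- assign_synergy_label(rep2$loewe, config$synergy_threshold)
    samples <- rbind(samples, rep2)
    rownames(samples) <- NULL
  }
  list(dataset = deml_dataset(samples, store), truth = truth, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits the drug feature table, the cell-line feature table and the
#' combination table as CSV, plus a ground-truth JSON sidecar (embeddings,
#' score-function weights, DDI pairs, calibrated intercept) for
#' parameter-recovery tests.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("drug_features.csv", "cell_features.csv",
                            "combinations.csv", "ground_truth.json"))
  write_feature_table(cohort$dataset$store$drug, paths[1], id_col = "drug_id")
  write_feature_table(cohort$dataset$store$cell, paths[2], id_col = "cell_id")
  utils::write.csv(cohort$dataset$samples, paths[3], row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$ddi_pairs <- gsub("\r", "|", truth$ddi_pairs, fixed = TRUE)
  jsonlite::write_json(unclass(truth), paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
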