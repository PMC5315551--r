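#' The cortico-basal-ganglia inhibition model space
#'
#' Six nodes: bilateral inferior frontal gyrus (IFG, MNI {+/-54; 12; 18}),
#' bilateral dorsolateral prefrontal cortex (DLPFC, {+/-37; 27; 39}), medial
#' preSMA/dACC ({0; -6; 56}) and the basal ganglia (BG) modeled as a single
#' hidden source. Fourteen connections: per hemisphere IFG->DLPFC forward
#' and DLPFC->IFG backward (4), DLPFC->preSMA/dACC backward feedback (2),
#' bidirectional lateral pairs preSMA/dACC<->BG (2) and IFG<->BG per
#' hemisphere (4), and undirected interhemispheric lateral connections
#' IFG-IFG and DLPFC-DLPFC (2). The visual cue drives the IFG and DLPFC
#' bilaterally.
#'
#' Nine condition-modulation models are crossed from the cortical partner
#' whose BG connections may change between stimulation conditions (IFG only,
#' preSMA/dACC only, or both) and the direction of the modulated edges
#' (afferent cortex->BG, efferent BG->cortex, or both); only BG-involving
#' extrinsic connections are ever modulated, intrinsic connections stay
#' fixed. The models are partitioned into three families of three by
#' cortical partner.
#'
#' @return object of class `model_space` with `nodes` (name, x, y, z,
#'   hidden), `edges` (from, to, type, directed, id), `input_nodes`,
#'   `models` (named list of modulated-edge-id masks) and `families`
#'   (named list of model-name vectors).
#' @export
build_model_space <- function() {
  nodes <- data.frame(
    name = c("L_IFG", "R_IFG", "L_DLPFC", "R_DLPFC", "preSMA_dACC", "BG"),
    x = c(-54, 54, -37, 37, 0, NA),
    y = c(12, 12, 27, 27, -6, NA),
    z = c(18, 18, 39, 39, 56, NA),
    hidden = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)

  edge <- function(from, to, type, directed = TRUE)
    data.frame(from = from, to = to, type = type, directed = directed,
               stringsAsFactors = FALSE)
  edges <- rbind(
    edge("L_IFG", "L_DLPFC", "forward"),
    edge("L_DLPFC", "L_IFG", "backward"),
    edge("R_IFG", "R_DLPFC", "forward"),
    edge("R_DLPFC", "R_IFG", "backward"),
    edge("L_DLPFC", "preSMA_dACC", "backward"),
    edge("R_DLPFC", "preSMA_dACC", "backward"),
    edge("preSMA_dACC", "BG", "lateral"),
    edge("BG", "preSMA_dACC", "lateral"),
    edge("L_IFG", "BG", "lateral"),
    edge("BG", "L_IFG", "lateral"),
    edge("R_IFG", "BG", "lateral"),
    edge("BG", "R_IFG", "lateral"),
    edge("L_IFG", "R_IFG", "lateral", directed = FALSE),
    edge("L_DLPFC", "R_DLPFC", "lateral", directed = FALSE))
  edges$id <- paste0(edges$from, ifelse(edges$directed, "->", "--"), edges$to)

  ifg_aff <- c("L_IFG->BG", "R_IFG->BG")
  ifg_eff <- c("BG->L_IFG", "BG->R_IFG")
  sma_aff <- "preSMA_dACC->BG"
  sma_eff <- "BG->preSMA_dACC"
  masks <- list(
    IFG_afferent = ifg_aff,
    IFG_efferent = ifg_eff,
    IFG_both = c(ifg_aff, ifg_eff),
    preSMA_afferent = sma_aff,
    preSMA_efferent = sma_eff,
    preSMA_both = c(sma_aff, sma_eff),
    both_afferent = c(ifg_aff, sma_aff),
    both_efferent = c(ifg_eff, sma_eff),
    both_both = c(ifg_aff, ifg_eff, sma_aff, sma_eff))
  families <- list(
    IFG = c("IFG_afferent", "IFG_efferent", "IFG_both"),
    preSMA = c("preSMA_afferent", "preSMA_efferent", "preSMA_both"),
    both = c("both_afferent", "both_efferent", "both_both"))

  structure(list(nodes = nodes, edges = edges,
                 input_nodes = c("L_IFG", "R_IFG", "L_DLPFC", "R_DLPFC"),
                 models = masks, families = families),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("Model space: %d nodes (%d hidden), %d connections, %d models in %d families\n",
              nrow(x$nodes), sum(x$nodes$hidden), nrow(x$edges),
              length(x$models), length(x$families)))
  invisible(x)
}

#' Simulate a subjects x models log-evidence matrix
#'
#' A synthetic stand-in for per-subject free energies of fitted models: each
#' subject's generating model is the designated true model with probability
#' 1 - heterogeneity, otherwise uniform over the remaining models; its cell
#' receives `effect_nats` and all others 0, plus Normal(0, noise_nats)
#' noise per cell.
#'
#' @param space a [build_model_space()] (or any named list of models).
#' @param true_model model name most subjects are generated from.
#' @param effect_nats log-evidence advantage of the generating model, nats.
#' @param noise_nats sd of the additive evidence noise, nats.
#' @param n_subjects number of subjects.
#' @param heterogeneity fraction of subjects drawn from other models.
#' @param seed integer seed.
#' @return matrix `[subject x model]` with dimnames; the per-subject
#'   generating model is attached as attribute `"generating_model"`.
#' @export
simulate_evidences <- function(space, true_model, effect_nats = 10,
                               noise_nats = 1, n_subjects = 12,
                               heterogeneity = 0, seed = 1) {
  models <- if (inherits(space, "model_space")) names(space$models) else
    as.character(space)
  if (!true_model %in% models) stop("unknown true_model: ", true_model)
  stopifnot(effect_nats >= 0, heterogeneity >= 0, heterogeneity <= 1)
  set.seed(derive_seed(seed, "evidences"))
  gen <- ifelse(runif(n_subjects) < heterogeneity,
                sample(setdiff(models, true_model), n_subjects, replace = TRUE),
                true_model)
  lnE <- matrix(rnorm(n_subjects * length(models), 0, noise_nats),
                n_subjects, length(models),
                dimnames = list(sprintf("S%02d", seq_len(n_subjects)), models))
  lnE[cbind(seq_len(n_subjects), match(gen, models))] <-
    lnE[cbind(seq_len(n_subjects), match(gen, models))] + effect_nats
  attr(lnE, "generating_model") <- gen
  lnE
}

# softmax per row, numerically stable
row_softmax <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# Draw n Dirichlet(alpha) samples (rows), in chunks to bound memory, and
# return the frequency with which each coordinate — or each group sum when
# `groups` is a list of index vectors — attains the maximum.
dirichlet_argmax_freq <- function(alpha, n_samples, groups = NULL,
                                  chunk = 200000L) {
  K <- length(alpha)
  G <- if (is.null(groups)) K else length(groups)
  counts <- integer(G)
  left <- n_samples
  while (left > 0) {
    m <- min(left, chunk)
    g <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    if (!is.null(groups))
      g <- vapply(groups, function(ix) rowSums(g[, ix, drop = FALSE]),
                  numeric(m))
    w <- max.col(g, ties.method = "first")
    counts <- counts + tabulate(w, G)
    left <- left - m
  }
  counts / n_samples
}

#' Random-effects Bayesian model selection
#'
#' Treats the model a subject's data came from as a random effect with
#' population frequencies r ~ Dirichlet(alpha). The variational posterior is
#' iterated to a fixed point: subject-model assignment responsibilities
#' g_nk proportional to exp(lnE_nk + digamma(alpha_k) - digamma(sum alpha)),
#' then alpha = prior + sum_n g_nk, until max |delta alpha| < `tol` or
#' `max_iter` iterations. Exceedance probabilities — the posterior
#' probability that each model is the most frequent in the population — are
#' estimated by Monte-Carlo sampling of the Dirichlet posterior.
#'
#' @param lnE subjects x models log-evidence matrix, nats.
#' @param prior_alpha Dirichlet prior concentration per model (default 1,
#'   uniform; may be a vector).
#' @param n_samples Dirichlet draws for the exceedance estimate (>= 1e4).
#' @param seed seed for the exceedance sampling.
#' @param max_iter,tol convergence controls of the fixed-point iteration.
#' @return object of class `bms_result`: `alpha`, `expected_freq`
#'   (= alpha / sum alpha), `exceedance`, `assignments` (subjects x models
#'   responsibilities), `converged`, `n_iter`, `n_samples`, `seed`.
#' @export
rfx_bms <- function(lnE, prior_alpha = 1, n_samples = 1e6, seed = 1,
                    max_iter = 500, tol = 1e-6) {
  stopifnot(is.matrix(lnE), all(is.finite(lnE)),
            nrow(lnE) >= 1, ncol(lnE) >= 2)
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  K <- ncol(lnE)
  alpha0 <- rep_len(prior_alpha, K)
  if (any(alpha0 <= 0)) stop("prior_alpha must be > 0")
  alpha <- alpha0 + nrow(lnE) / K
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- sweep(lnE, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- row_softmax(lg)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged)
    warning("RFX-BMS fixed point not converged after ", max_iter, " iterations")
  names(alpha) <- colnames(lnE)
  set.seed(derive_seed(seed, "exceedance"))
  xp <- dirichlet_argmax_freq(alpha, n_samples)
  names(xp) <- colnames(lnE)
  structure(list(alpha = alpha, expected_freq = alpha / sum(alpha),
                 exceedance = xp, assignments = g, prior_alpha = alpha0,
                 converged = converged, n_iter = it, n_samples = n_samples,
                 seed = seed),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$alpha), "models",
      if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- data.frame(alpha = round(x$alpha, 3),
                    expected_freq = round(x$expected_freq, 3),
                    exceedance = round(x$exceedance, 3))
  print(tab)
  invisible(x)
}

#' Family-level random-effects inference
#'
#' Runs [rfx_bms()] with the per-model prior rescaled to
#' `prior_alpha / |family|` so that families are a priori equiprobable
#' regardless of how many models they contain, then estimates each family's
#' exceedance probability as the Monte-Carlo frequency with which the summed
#' Dirichlet mass of its models exceeds every other family's.
#'
#' @param lnE subjects x models log-evidence matrix.
#' @param partition named list of model-name (or column-index) vectors
#'   covering all models without overlap, e.g. `space$families`.
#' @param prior_alpha prior concentration per family.
#' @param n_samples,seed exceedance sampling controls.
#' @return object of class `family_bms`: `family_exceedance`,
#'   `family_expected` (summed expected frequencies), `within_family`
#'   (model posteriors renormalized inside each family), plus the
#'   underlying `bms` result.
#' @export
family_bms <- function(lnE, partition, prior_alpha = 1, n_samples = 1e6,
                       seed = 1) {
  models <- colnames(lnE)
  idx <- lapply(partition, function(f) {
    ix <- if (is.character(f)) match(f, models) else as.integer(f)
    if (anyNA(ix) || length(ix) == 0) stop("empty or unknown family member")
    ix
  })
  all_ix <- sort(unname(unlist(idx)))
  if (!identical(all_ix, seq_len(ncol(lnE))))
    stop("partition must cover all models exactly once")
  prior <- numeric(ncol(lnE))
  for (f in idx) prior[f] <- prior_alpha / length(f)
  bms <- rfx_bms(lnE, prior_alpha = prior, n_samples = n_samples, seed = seed)
  set.seed(derive_seed(seed, "family_exceedance"))
  fx <- dirichlet_argmax_freq(bms$alpha, n_samples, groups = idx)
  names(fx) <- names(partition)
  fam_exp <- vapply(idx, function(f) sum(bms$expected_freq[f]), numeric(1))
  within <- lapply(idx, function(f) {
    w <- bms$expected_freq[f]
    w / sum(w)
  })
  structure(list(family_exceedance = fx, family_expected = fam_exp,
                 within_family = within, bms = bms,
                 n_samples = n_samples, seed = seed),
            class = "family_bms")
}

#' @export
print.family_bms <- function(x, ...) {
  cat("Family-level RFX-BMS\n")
  print(round(rbind(exceedance = x$family_exceedance,
                    expected = x$family_expected), 3))
  invisible(x)
}

#' Simulate per-subject connection strengths for a model set
#'
#' Synthetic stand-in for fitted connectivity parameters (log scaling
#' factors). Each subject draws a baseline strength per connection shared
#' across models and conditions; the ON condition shifts the strength of
#' `target_connection` by `log(on_scale)` plus between-subject noise, but
#' only in models whose modulation mask contains that connection (intrinsic
#' to the others, ON equals OFF). A small model-specific wobble keeps model
#' parameters from being exactly collinear.
#'
#' @param space a [build_model_space()].
#' @param n_subjects number of subjects.
#' @param target_connection edge id whose ON/OFF modulation is simulated
#'   (default the BG efferent to the right IFG).
#' @param on_scale multiplicative ON/OFF effect on that connection's
#'   (exponentiated) strength; 0.7 means a 30% decrease under stimulation.
#' @param base_mean,base_sd baseline log-strength distribution.
#' @param subj_sd between-subject sd of the modulation, log units.
#' @param model_sd sd of the model-specific wobble.
#' @param seed integer seed.
#' @return long data.frame: subject, model, connection, condition, strength
#'   (log units).
#' @export
simulate_dcm_params <- function(space, n_subjects = 12,
                                target_connection = "BG->R_IFG",
                                on_scale = 0.7, base_mean = 0.2,
                                base_sd = 0.3, subj_sd = 0.1,
                                model_sd = 0.05, seed = 1) {
  stopifnot(inherits(space, "model_space"))
  if (!target_connection %in% space$edges$id)
    stop("unknown connection: ", target_connection)
  set.seed(derive_seed(seed, "dcm_params"))
  conns <- space$edges$id
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    base <- rnorm(length(conns), base_mean, base_sd)
    names(base) <- conns
    shift <- log(on_scale) + rnorm(1, 0, subj_sd)
    for (m in names(space$models)) {
      wob <- rnorm(length(conns), 0, model_sd)
      off <- base + wob
      on <- off
      if (target_connection %in% space$models[[m]])
        on[target_connection] <- on[target_connection] + shift
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, model = m, connection = conns,
        condition = rep(c("OFF", "ON"), each = length(conns)),
        strength = c(off, on), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bayesian model averaging within a family
#'
#' Averages per-subject connection strengths over the models of the winning
#' family, each subject using its own posterior model probabilities (softmax
#' of its log-evidences restricted to the family, uniform within-family
#' prior; weights sum to 1 per subject). The group summary per connection
#' and condition is the exponential of the mean averaged log-strength over
#' subjects, and each connection's ON vs OFF difference is tested with a
#' paired t-test across subjects.
#'
#' @param subject_params long data.frame as from [simulate_dcm_params()]:
#'   subject, model, connection, condition, strength (log units).
#' @param lnE subjects x models log-evidence matrix (row names must match
#'   the subjects in `subject_params`).
#' @param family character vector of model names to average over (e.g. the
#'   winning family from [family_bms()]).
#' @return object of class `bma_result`: `subject_strengths` (subject x
#'   connection x condition averaged log-strengths, long), `group_summary`
#'   (connection x condition, exp of the subject mean), `tests` (per
#'   connection paired ON vs OFF), `weights` (subject x model).
#' @export
bma <- function(subject_params, lnE, family) {
  stopifnot(is.data.frame(subject_params), is.matrix(lnE))
  family <- as.character(family)
  if (!all(family %in% colnames(lnE)))
    stop("family members missing from the evidence matrix")
  have <- unique(subject_params$model)
  if (!all(family %in% have))
    stop("parameters missing for family model(s): ",
         paste(setdiff(family, have), collapse = ", "))
  subjects <- rownames(lnE)
  w <- row_softmax(lnE[, family, drop = FALSE])
  rownames(w) <- subjects

  sp <- subject_params[subject_params$model %in% family, ]
  if (!all(subjects %in% sp$subject))
    stop("parameters missing for some subjects in the evidence matrix")
  sp$w <- w[cbind(match(sp$subject, subjects), match(sp$model, family))]
  sp$wx <- sp$w * sp$strength
  agg <- aggregate(wx ~ subject + connection + condition, data = sp, FUN = sum)
  names(agg)[names(agg) == "wx"] <- "strength"

  grp <- aggregate(strength ~ connection + condition, data = agg, FUN = mean)
  grp$group_strength <- exp(grp$strength)
  grp$strength <- NULL

  conns <- unique(agg$connection)
  tests <- do.call(rbind, lapply(conns, function(cn) {
    a <- agg[agg$connection == cn, ]
    on <- a$strength[a$condition == "ON"][order(a$subject[a$condition == "ON"])]
    off <- a$strength[a$condition == "OFF"][order(a$subject[a$condition == "OFF"])]
    paired_compare(on, off, test = "paired_t", measure = cn)
  }))
  structure(list(subject_strengths = agg, group_summary = grp,
                 tests = tests, weights = w, family = family),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("BMA over family {", paste(x$family, collapse = ", "), "}\n")
  sig <- x$tests[order(x$tests$p_value), c("measure", "statistic", "p_value")]
  print(utils::head(sig, 5), row.names = FALSE)
  invisible(x)
}
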