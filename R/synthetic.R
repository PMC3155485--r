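#' Default site-distance table for the six-hospital system
#'
#' A synthetic but plausible symmetric km table over the six named
#' hospital sites, spanning 0-77 km (one outlying mountain site accounts
#' for the long distances). The study's true road distances are not
#' published; any user table in the same format can replace this one.
#'
#' @return A [site_distance_table()].
#' @export
default_site_distances <- function() {
  site_distance_table(data.frame(
    site_a = c("Bellaria", "Bellaria", "Bellaria", "Bellaria", "Bellaria",
               "Budrio", "Budrio", "Budrio", "Budrio",
               "Maggiore", "Maggiore", "Maggiore",
               "Porretta", "Porretta", "Bentivoglio"),
    site_b = c("Budrio", "Maggiore", "Porretta", "Bentivoglio",
               "Mazzacorati/Roncati",
               "Maggiore", "Porretta", "Bentivoglio", "Mazzacorati/Roncati",
               "Porretta", "Bentivoglio", "Mazzacorati/Roncati",
               "Bentivoglio", "Mazzacorati/Roncati", "Mazzacorati/Roncati"),
    km = c(20, 8, 55, 25, 5,
           22, 70, 30, 22,
           50, 20, 9,
           77, 52, 28),
    stringsAsFactors = FALSE
  ))
}

#' Configuration for the synthetic sociometric study generator
#'
#' Defaults emulate the surveyed 297-physician system: attribute marginals
#' (truncated-normal ages/tenures, categorical affiliation shares, 4-level
#' EBM attitude with mean ~2.98 and SD ~0.56, negative-binomial publication
#' counts), a logistic dyadic tie model whose planted coefficients `theta`
#' carry the reported effect signs on the homophily covariates, a baseline
#' `theta0` placing overall arc density in the ~1.7% regime, and a
#' strength distribution giving mean nonzero strength ~3.3 (so valued
#' density ~5.7%). Arcs are drawn independently per ordered dyad;
#' `reciprocity_boost` (extra log-odds on an arc whose reverse arc was
#' already drawn) is available to emulate the observed ~61% arc
#' reciprocity, and defaults to 0.
#'
#' @param n_nodes Number of physicians (>= 10; default 297).
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @param age,years_since_graduation,tenure_nhs,tenure_lha Truncated-normal
#'   specs `list(mean, sd, lo, hi)`, in years (rounded to whole years).
#' @param gender_p_male Bernoulli probability of "M".
#' @param ebm_probs,specialization_probs,hospital_probs,directorate_probs
#'   Category probabilities (named by level, summing to 1).
#' @param publications `list(mean, dispersion)` for the negative-binomial
#'   publication count.
#' @param coauthor_rate Expected co-authored partners per node (a rate of 3
#'   at n = 297 gives mean co-authorship cell ~0.01).
#' @param coauthor_same_directorate_boost Sampling-weight multiplier for
#'   same-directorate pairs when drawing co-author pairs.
#' @param directorate_specialization_coupling Probability, per node, that
#'   specialization is set to the directorate-typical specialty instead of
#'   an independent draw (0 = fully independent attributes).
#' @param site_distances A [site_distance_table()] over the hospital
#'   levels.
#' @param theta0 Baseline log-odds of an arc.
#' @param theta Named planted coefficients on the dyadic covariate panel
#'   (names must be [default_predictors()] names).
#' @param strength_probs Probability vector over strengths 1-5 given an
#'   arc.
#' @param reciprocity_boost Extra log-odds when the reverse arc exists.
#' @return Validated configuration, classed `"synth_config"`.
#' @export
synth_config <- function(
    n_nodes = 297,
    seed = 1L,
    age = list(mean = 47.01, sd = 8.01, lo = 30, hi = 67),
    years_since_graduation = list(mean = 27.05, sd = 8.69, lo = 7, hi = 55),
    tenure_nhs = list(mean = 16.01, sd = 9.74, lo = 1, hi = 41),
    tenure_lha = list(mean = 10.95, sd = 7.94, lo = 1, hi = 37),
    gender_p_male = 158 / 297,
    ebm_probs = c("never" = 0.01, "rarely" = 0.13, "sometimes" = 0.73,
                  "often/very often" = 0.13),
    specialization_probs = c("medical" = 0.6908, "surgical" = 0.1053,
                             "obstetrics-gynaecology" = 0.1283,
                             "paediatrics" = 0.0757),
    hospital_probs = c("Bellaria" = 0.4074, "Budrio" = 0.0303,
                       "Maggiore" = 0.3771, "Porretta" = 0.0202,
                       "Bentivoglio" = 0.0673,
                       "Mazzacorati/Roncati" = 0.0976),
    directorate_probs = c("Neuroscience" = 0.5859, "Oncology" = 0.1616,
                          "Maternal-Health" = 0.2525),
    publications = list(mean = 4.27, dispersion = 0.22),
    coauthor_rate = 3,
    coauthor_same_directorate_boost = 4,
    directorate_specialization_coupling = 0,
    site_distances = default_site_distances(),
    theta0 = -4.46,
    theta = c(ebm_attitude_same = 0.25, years_since_graduation_diff = -0.015,
              specialization_same = 0.9, managerial_role_same = -0.25,
              hospital_same = 0.6, directorate_same = 0.4,
              n_publications_diff = -0.01, co_authorship = 1.5,
              geo_distance = -0.02),
    strength_probs = c(0.05, 0.15, 0.35, 0.31, 0.14),
    reciprocity_boost = 0) {
  cfg <- list(n_nodes = n_nodes, seed = seed, age = age,
              years_since_graduation = years_since_graduation,
              tenure_nhs = tenure_nhs, tenure_lha = tenure_lha,
              gender_p_male = gender_p_male, ebm_probs = ebm_probs,
              specialization_probs = specialization_probs,
              hospital_probs = hospital_probs,
              directorate_probs = directorate_probs,
              publications = publications, coauthor_rate = coauthor_rate,
              coauthor_same_directorate_boost = coauthor_same_directorate_boost,
              directorate_specialization_coupling = directorate_specialization_coupling,
              site_distances = site_distances, theta0 = theta0,
              theta = theta, strength_probs = strength_probs,
              reciprocity_boost = reciprocity_boost)
  cfg <- validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_nodes < 10) stop("n_nodes must be >= 10")
  schema <- default_schema()
  probsets <- list(ebm_probs = "ebm_attitude",
                   specialization_probs = "specialization",
                   hospital_probs = "hospital",
                   directorate_probs = "directorate")
  for (nm in names(probsets)) {
    p <- cfg[[nm]]
    # printed percentages may round to slightly off 1; renormalize
    if (abs(sum(p) - 1) > 1e-3 || any(p < 0)) {
      stop(sprintf("%s must be non-negative and sum to 1", nm))
    }
    cfg[[nm]] <- p / sum(p)
    if (!setequal(names(p), schema[[probsets[[nm]]]])) {
      stop(sprintf("%s must be named by the %s levels", nm, probsets[[nm]]))
    }
  }
  if (abs(sum(cfg$strength_probs) - 1) > 1e-3 ||
      length(cfg$strength_probs) != 5 || any(cfg$strength_probs < 0)) {
    stop("strength_probs must be 5 non-negative probabilities summing to 1")
  }
  cfg$strength_probs <- cfg$strength_probs / sum(cfg$strength_probs)
  for (nm in c("age", "years_since_graduation", "tenure_nhs", "tenure_lha")) {
    s <- cfg[[nm]]
    if (s$sd <= 0 || s$lo >= s$hi) {
      stop(sprintf("invalid truncated-normal spec for %s", nm))
    }
  }
  if (cfg$gender_p_male < 0 || cfg$gender_p_male > 1) {
    stop("gender_p_male must be a probability")
  }
  if (cfg$publications$mean < 0 || cfg$publications$dispersion <= 0) {
    stop("invalid publication-count parameters")
  }
  if (cfg$coauthor_rate < 0) stop("coauthor_rate must be >= 0")
  bad <- setdiff(names(cfg$theta), default_predictors()$name)
  if (length(bad) > 0) {
    stop(sprintf("theta names do not resolve to panel covariates: %s",
                 paste(bad, collapse = ", ")))
  }
  cfg
}

rtrunc_norm <- function(n, spec) {
  lo <- stats::pnorm((spec$lo - spec$mean) / spec$sd)
  hi <- stats::pnorm((spec$hi - spec$mean) / spec$sd)
  stats::qnorm(stats::runif(n, lo, hi)) * spec$sd + spec$mean
}

# Draw attributes using the current RNG stream.
.generate_attributes <- function(cfg) {
  n <- cfg$n_nodes
  schema <- default_schema()
  draw_cat <- function(p, lev) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = lev)
  }
  df <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age = round(rtrunc_norm(n, cfg$age)),
    gender = draw_cat(c(M = cfg$gender_p_male, F = 1 - cfg$gender_p_male),
                      schema$gender),
    ebm_attitude = draw_cat(cfg$ebm_probs, schema$ebm_attitude),
    years_since_graduation = round(rtrunc_norm(n, cfg$years_since_graduation)),
    specialization = draw_cat(cfg$specialization_probs, schema$specialization),
    tenure_nhs = round(rtrunc_norm(n, cfg$tenure_nhs)),
    tenure_lha = round(rtrunc_norm(n, cfg$tenure_lha)),
    managerial_role = draw_cat(c(manager = 51 / 297, professional = 246 / 297),
                               schema$managerial_role),
    hospital = draw_cat(cfg$hospital_probs, schema$hospital),
    directorate = draw_cat(cfg$directorate_probs, schema$directorate),
    n_publications = stats::rnbinom(n, size = cfg$publications$dispersion,
                                    mu = cfg$publications$mean),
    stringsAsFactors = FALSE
  )
  cpl <- cfg$directorate_specialization_coupling
  if (cpl > 0) {
    typical <- c("Neuroscience" = "medical", "Oncology" = "medical",
                 "Maternal-Health" = "obstetrics-gynaecology")
    hit <- stats::runif(n) < cpl
    df$specialization[hit] <-
      factor(typical[as.character(df$directorate[hit])],
             levels = schema$specialization)
  }
  roster(df)
}

#' Generate a synthetic roster of physician attributes
#'
#' Attributes are drawn independently per node from the configured
#' marginal distributions (optionally coupling specialization to
#' directorate); deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A [roster()] of `config$n_nodes` individuals.
#' @export
generate_attributes <- function(config, seed = config$seed) {
  set.seed(as.integer(seed))
  .generate_attributes(config)
}

.generate_coauthorship <- function(roster, cfg) {
  ids <- roster_ids(roster)
  n <- length(ids)
  pubs <- stats::setNames(rep(list(character(0)), n), ids)
  lambda <- n * cfg$coauthor_rate / 2
  if (lambda > 0) {
    k <- stats::rpois(1, lambda)
    if (k > 0) {
      pr <- t(utils::combn(n, 2))
      same_dir <- as.character(roster$directorate[pr[, 1]]) ==
        as.character(roster$directorate[pr[, 2]])
      w <- ifelse(!is.na(same_dir) & same_dir,
                  cfg$coauthor_same_directorate_boost, 1)
      k <- min(k, nrow(pr))
      pick <- sample.int(nrow(pr), k, prob = w)
      for (idx in seq_along(pick)) {
        pub <- sprintf("PUB%05d", idx)
        a <- ids[pr[pick[idx], 1]]
        b <- ids[pr[pick[idx], 2]]
        pubs[[a]] <- c(pubs[[a]], pub)
        pubs[[b]] <- c(pubs[[b]], pub)
      }
    }
  }
  pubs
}

#' Generate synthetic co-authorship records
#'
#' Draws a Poisson number of co-author pairs (expected
#' `n_nodes * coauthor_rate / 2`), sampled with extra weight on
#' same-directorate pairs, each pair sharing one synthetic publication id.
#'
#' @inheritParams generate_attributes
#' @param roster A [roster()].
#' @return Named list of publication-id vectors per node.
#' @export
generate_coauthorship <- function(roster, config, seed = config$seed) {
  set.seed(as.integer(seed))
  .generate_coauthorship(roster, config)
}

.generate_network <- function(roster, cfg, publications = NULL) {
  ids <- roster_ids(roster)
  n <- length(ids)
  theta <- cfg$theta[cfg$theta != 0]
  eta <- matrix(cfg$theta0, n, n, dimnames = list(ids, ids))
  if (length(theta) > 0) {
    need_pubs <- "co_authorship" %in% names(theta)
    if (need_pubs && is.null(publications)) {
      stop("theta references co_authorship: publications required")
    }
    panel <- covariate_panel(roster, publications = publications,
                             site_distances = cfg$site_distances,
                             predictors = names(theta))
    for (nm in names(theta)) {
      v <- panel[[nm]]$values
      if (any(panel[[nm]]$mask)) {
        stop(sprintf("covariate '%s' has masked dyads; the tie model needs complete attributes",
                     nm))
      }
      eta <- eta + theta[[nm]] * v
    }
  }
  p <- stats::plogis(eta)
  up <- upper.tri(p)
  lo <- lower.tri(p)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  A[up] <- (stats::runif(sum(up)) < p[up]) * 1L
  p_lo <- p[lo]
  if (cfg$reciprocity_boost != 0) {
    rev_arc <- t(A)[lo]
    p_lo <- stats::plogis(eta[lo] + cfg$reciprocity_boost * rev_arc)
  }
  A[lo] <- (stats::runif(sum(lo)) < p_lo) * 1L
  diag(A) <- 0L
  m <- A
  n_arcs <- sum(A)
  if (n_arcs > 0) {
    m[A == 1L] <- sample(1:5, n_arcs, replace = TRUE,
                         prob = cfg$strength_probs)
  }
  valued_network(m)
}

#' Generate a synthetic valued collaboration network
#'
#' Each ordered dyad receives an arc with probability
#' `plogis(theta0 + sum(theta_k * x_k[i, j]))` over the planted dyadic
#' covariates; given an arc, its strength is drawn from `strength_probs`.
#' With `reciprocity_boost != 0`, the arc opposite an already-drawn arc
#' gets the boost added to its log-odds.
#'
#' @inheritParams generate_coauthorship
#' @param publications Co-authorship records (required iff `theta` places a
#'   nonzero coefficient on `co_authorship`).
#' @return A [valued_network()].
#' @export
generate_network <- function(roster, config, publications = NULL,
                             seed = config$seed) {
  set.seed(as.integer(seed))
  .generate_network(roster, config, publications)
}

#' Simulate a complete synthetic study
#'
#' Runs the three generators off one seeded RNG stream: attributes, then
#' co-authorship, then the tie network. The output is byte-deterministic
#' given (config, seed) and feeds the pipeline exactly like ingested
#' survey data.
#'
#' @inheritParams generate_attributes
#' @return List with `roster`, `publications`, `network`,
#'   `site_distances`, `config`.
#' @export
simulate_study <- function(config, seed = config$seed) {
  set.seed(as.integer(seed))
  roster <- .generate_attributes(config)
  pubs <- .generate_coauthorship(roster, config)
  net <- .generate_network(roster, config, pubs)
  list(roster = roster, publications = pubs, network = net,
       site_distances = config$site_distances, config = config)
}

#' Planted-effect recovery and calibration experiment
#'
#' Repeatedly simulates a study, builds the covariate panel, runs
#' [qap_test()] on the valued network, and aggregates per predictor: the
#' rate at which the planted sign is recovered by the standardized
#' coefficient, the two-sided rejection rate at `alpha` (power for planted
#' nonzero effects, type-I error for planted zeros).
#'
#' @param config A [synth_config()] defining the planted tie model.
#' @param n_replicates Number of simulated studies (>= 50 for a stable
#'   report; smaller values are allowed for smoke tests).
#' @param alpha Two-sided significance level.
#' @param n_perm Permutations per QAP test.
#' @param method Passed to [qap_test()].
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param predictors Predictor spec (default: the full panel).
#' @return Object of class `"recovery_report"`: a per-predictor data frame
#'   plus experiment metadata.
#' @export
recovery_experiment <- function(config, n_replicates = 50, alpha = 0.05,
                                n_perm = 500, method = "dsp", seed,
                                predictors = default_predictors()) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  spec <- if (is.character(predictors)) {
    dp <- default_predictors()
    dp[match(predictors, dp$name), , drop = FALSE]
  } else predictors
  terms <- spec$name
  signs <- matrix(NA_real_, n_replicates, length(terms),
                  dimnames = list(NULL, terms))
  pvals <- matrix(NA_real_, n_replicates, length(terms),
                  dimnames = list(NULL, terms))
  for (r in seq_len(n_replicates)) {
    sim <- simulate_study(config, seed = rep_seeds[r])
    panel <- covariate_panel(sim$roster, publications = sim$publications,
                             site_distances = sim$site_distances,
                             predictors = terms)
    res <- qap_test(sim$network, panel, n_perm = n_perm, method = method,
                    seed = rep_seeds[r])
    signs[r, ] <- sign(res$coefficients$std_coef)
    pvals[r, ] <- res$coefficients$p_two_sided
  }
  theta <- stats::setNames(rep(0, length(terms)), terms)
  planted <- config$theta[names(config$theta) %in% terms]
  theta[names(planted)] <- planted
  report <- data.frame(
    term = terms,
    theta = unname(theta),
    sign_recovery_rate = vapply(terms, function(t) {
      if (theta[[t]] == 0) NA_real_ else mean(signs[, t] == sign(theta[[t]]))
    }, numeric(1)),
    rejection_rate = colMeans(pvals < alpha),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  structure(list(report = report, pvalues = pvals,
                 n_replicates = n_replicates, alpha = alpha,
                 n_perm = n_perm, method = method, seed = as.integer(seed)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery experiment: %d replicates, %d permutations (%s), alpha %.2f\n",
              x$n_replicates, x$n_perm, x$method, x$alpha))
  print(x$report, row.names = FALSE)
  invisible(x)
}
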