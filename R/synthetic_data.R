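#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every parameter of the three generators
#' (\code{\link{simulateNormalTissuePanel}}, \code{\link{simulateTumorCohort}},
#' \code{\link{simulateIHCTable}}). Expression is drawn on the log scale:
#' silent/background states and ectopically active states are two log-normal
#' modes, mimicking the bimodal TPM distribution of normally silent genes
#' that are switched on in a subset of tumours.
#'
#' The survival model is a constant-hazard (exponential) proportional-hazards
#' model: hazard = \code{baseline_hazard} * exp(sum of per-gene effects over
#' activated true prognostic genes + covariate effects), with administrative
#' censoring at \code{censor_time} months plus independent exponential
#' dropout at rate \code{dropout_rate}.
#'
#' Planted tissue-specific genes take their home tissue from
#' \code{germline_tissues}: a gene that is predominant in a somatic tissue
#' could not also be silent in all non-germline somatic tissues, and the
#' biomarkers this pipeline targets are testis/placenta-restricted genes.
#'
#' @param n_tissues number of normal tissues in the panel.
#' @param n_samples_per_tissue samples per tissue.
#' @param n_genes total genes simulated.
#' @param n_tissue_specific number of planted tissue-predominant silent genes
#'   (the first \code{n_tissue_specific} gene IDs).
#' @param germline_tissues names of tissues treated as germline/placenta.
#' @param n_patients tumour cohort size.
#' @param n_ectopic_candidates number of genes eligible for ectopic
#'   activation in tumours (the first \code{n_ectopic_candidates} gene IDs).
#' @param n_true_prognostic number of candidates whose activation carries a
#'   hazard effect (the first \code{n_true_prognostic} gene IDs).
#' @param activation_fraction per-gene per-patient activation probability.
#' @param log_hazard_per_activation log hazard ratio per activated true
#'   prognostic gene.
#' @param baseline_hazard events per month for a reference patient.
#' @param censor_time administrative censoring horizon, months.
#' @param dropout_rate rate (per month) of independent censoring.
#' @param covariate_effects named numeric vector of log-hazard effects for
#'   clinical covariates; recognised names: \code{age} (per decade above 60),
#'   \code{gender} (male vs female), \code{stage_late}, \code{hpv_positive},
#'   \code{site_tbot}.
#' @param background_log_mean,background_log_sd log-normal parameters of the
#'   silent/background expression state.
#' @param active_log_mean,active_log_sd log-normal parameters of the active
#'   state.
#' @param hpv_activation_fraction optional activation fraction used for
#'   HPV-positive patients instead of \code{activation_fraction} (to emulate
#'   cohorts where HPV-positive tumours are almost universally panel
#'   positive); \code{NA} means no HPV coupling.
#' @param ihc_coupling strength in [0,1] of the coupling between true
#'   activation and IHC staining: probability that an activated marker is
#'   scored from the high-staining distribution (0 = staining independent of
#'   activation).
#' @param seed integer seed; each generator expands it into its own
#'   substream so adding one generator call does not perturb the others.
#' @return A validated list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(n_patients = 100, seed = 7)
#' cfg$activation_fraction
#' @export
simConfig <- function(
        n_tissues = 30L,
        n_samples_per_tissue = 5L,
        n_genes = 1000L,
        n_tissue_specific = 50L,
        germline_tissues = c("testis", "ovary", "placenta"),
        n_patients = 200L,
        n_ectopic_candidates = 50L,
        n_true_prognostic = 3L,
        activation_fraction = 0.4,
        log_hazard_per_activation = log(2.5),
        baseline_hazard = 0.01,
        censor_time = 120,
        dropout_rate = 0.003,
        covariate_effects = c(age = 0.2, stage_late = 0.5),
        background_log_mean = log(0.1),
        background_log_sd = 0.8,
        active_log_mean = log(50),
        active_log_sd = 0.5,
        hpv_activation_fraction = NA_real_,
        ihc_coupling = 0.9,
        seed = 1L) {
    cfg <- list(
        n_tissues = as.integer(n_tissues),
        n_samples_per_tissue = as.integer(n_samples_per_tissue),
        n_genes = as.integer(n_genes),
        n_tissue_specific = as.integer(n_tissue_specific),
        germline_tissues = as.character(germline_tissues),
        n_patients = as.integer(n_patients),
        n_ectopic_candidates = as.integer(n_ectopic_candidates),
        n_true_prognostic = as.integer(n_true_prognostic),
        activation_fraction = activation_fraction,
        log_hazard_per_activation = log_hazard_per_activation,
        baseline_hazard = baseline_hazard,
        censor_time = censor_time,
        dropout_rate = dropout_rate,
        covariate_effects = covariate_effects,
        background_log_mean = background_log_mean,
        background_log_sd = background_log_sd,
        active_log_mean = active_log_mean,
        active_log_sd = active_log_sd,
        hpv_activation_fraction = hpv_activation_fraction,
        ihc_coupling = ihc_coupling,
        seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

#' Validate a SimConfig, naming the offending field
#'
#' @param cfg a \code{SimConfig}.
#' @return Invisibly \code{TRUE}; stops with a configuration error otherwise.
#' @export
validateSimConfig <- function(cfg) {
    bad <- function(field, why)
        stop("invalid SimConfig field '", field, "': ", why, call. = FALSE)
    counts <- c("n_tissues", "n_samples_per_tissue", "n_genes", "n_patients")
    for (f in counts)
        if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
            bad(f, "must be a positive count")
    for (f in c("n_tissue_specific", "n_ectopic_candidates",
            "n_true_prognostic"))
        if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0L)
            bad(f, "must be a non-negative count")
    if (cfg$n_true_prognostic > cfg$n_ectopic_candidates)
        bad("n_true_prognostic", "exceeds n_ectopic_candidates")
    if (cfg$n_ectopic_candidates > cfg$n_genes)
        bad("n_ectopic_candidates", "exceeds n_genes")
    if (cfg$n_tissue_specific > cfg$n_genes)
        bad("n_tissue_specific", "exceeds n_genes")
    if (!is.numeric(cfg$activation_fraction) ||
            cfg$activation_fraction <= 0 || cfg$activation_fraction >= 1)
        bad("activation_fraction", "must lie strictly in (0, 1)")
    if (!is.numeric(cfg$baseline_hazard) || cfg$baseline_hazard <= 0)
        bad("baseline_hazard", "must be > 0")
    if (!is.numeric(cfg$censor_time) || cfg$censor_time < 0)
        bad("censor_time", "must be >= 0")
    if (!is.numeric(cfg$dropout_rate) || cfg$dropout_rate < 0)
        bad("dropout_rate", "must be >= 0")
    if (!is.na(cfg$hpv_activation_fraction) &&
            (cfg$hpv_activation_fraction <= 0 ||
             cfg$hpv_activation_fraction >= 1))
        bad("hpv_activation_fraction", "must lie strictly in (0, 1) or NA")
    if (cfg$ihc_coupling < 0 || cfg$ihc_coupling > 1)
        bad("ihc_coupling", "must lie in [0, 1]")
    if (length(cfg$germline_tissues) < 1L && cfg$n_tissue_specific > 0L)
        bad("germline_tissues", "at least one germline tissue is required")
    if (length(cfg$seed) != 1L || is.na(cfg$seed))
        bad("seed", "must be a single integer")
    invisible(TRUE)
}

# per-generator substreams: a fixed offset per generator keeps streams
# independent while staying below .Machine$integer.max
.subSeed <- function(seed, stream) {
    s <- (as.double(seed) * 7L + stream * 104729) %% 2147483629
    as.integer(s)
}

.geneIds <- function(n) sprintf("gene_%04d", seq_len(n))

#' Simulate a normal-tissue expression panel with planted specific genes
#'
#' The first \code{n_tissue_specific} genes are planted as
#' tissue-predominant silent genes: active-state expression in the samples
#' of one home tissue (assigned round-robin over the germline tissues) and
#' background-state expression everywhere else. All other genes are broadly
#' expressed, with a gene-level baseline drawn uniformly on the log scale
#' between the background and active means, so that no unplanted gene shows
#' the silent-elsewhere / predominant-somewhere structure.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with elements \code{panel} (a
#'   \linkS4class{NormalTissuePanel}) and \code{truth} (list with
#'   \code{tissue_specific_genes} and \code{home_tissue} named vector).
#' @examples
#' sim <- simulateNormalTissuePanel(simConfig(n_genes = 100,
#'     n_tissue_specific = 5, seed = 2))
#' sim$panel
#' @export
simulateNormalTissuePanel <- function(cfg) {
    validateSimConfig(cfg)
    set.seed(.subSeed(cfg$seed, 1L))
    nt <- cfg$n_tissues
    nspt <- cfg$n_samples_per_tissue
    ns <- nt * nspt
    genes <- .geneIds(cfg$n_genes)
    germ <- cfg$germline_tissues
    somaticNames <- sprintf("tissue_%02d", seq_len(max(nt - length(germ), 0L)))
    tissues <- c(germ[seq_len(min(length(germ), nt))], somaticNames)[seq_len(nt)]
    tissue <- rep(tissues, each = nspt)
    samples <- sprintf("%s_s%d", tissue, rep(seq_len(nspt), times = nt))

    x <- matrix(0, cfg$n_genes, ns, dimnames = list(genes, samples))
    nspec <- cfg$n_tissue_specific
    if (nspec > 0L) {
        germPresent <- intersect(germ, tissues)
        if (!length(germPresent))
            stop("no germline tissue present in the panel; cannot plant ",
                "tissue-specific genes", call. = FALSE)
        home <- rep_len(germPresent, nspec)
        names(home) <- genes[seq_len(nspec)]
        for (i in seq_len(nspec)) {
            inHome <- tissue == home[i]
            x[i, !inHome] <- stats::rlnorm(sum(!inHome),
                cfg$background_log_mean, cfg$background_log_sd)
            x[i, inHome] <- stats::rlnorm(sum(inHome),
                cfg$active_log_mean, cfg$active_log_sd)
        }
    } else {
        home <- stats::setNames(character(0), character(0))
    }
    nbg <- cfg$n_genes - nspec
    if (nbg > 0L) {
        baseline <- stats::runif(nbg, cfg$background_log_mean,
            cfg$active_log_mean)
        x[nspec + seq_len(nbg), ] <- matrix(stats::rlnorm(nbg * ns,
            rep(baseline, ns), cfg$background_log_sd), nbg, ns)
    }
    panel <- NormalTissuePanel(x, tissue = tissue, germlineTissues = germ)
    list(panel = panel,
        truth = list(tissue_specific_genes = genes[seq_len(nspec)],
            home_tissue = home))
}

.truncNorm <- function(n, mean, sd, lo, hi) {
    z <- stats::rnorm(n, mean, sd)
    pmin(pmax(z, lo), hi)
}

#' Simulate a tumour cohort with survival driven by ectopic activations
#'
#' The first \code{n_ectopic_candidates} genes are candidate ectopic genes:
#' per patient each is activated with probability
#' \code{activation_fraction} and its expression is drawn from the active
#' log-normal mode if activated, the background mode otherwise. Survival is
#' exponential with hazard
#' \code{baseline_hazard * exp(beta * n_true_activations + covariates)},
#' where only the first \code{n_true_prognostic} candidates carry the
#' per-activation effect \code{log_hazard_per_activation}. Censoring is the
#' minimum of the administrative horizon and an independent exponential
#' dropout. Remaining genes are broadly expressed background genes.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{cohort} (a \linkS4class{TumorCohort}) and
#'   \code{truth} (activation matrix over candidate genes, the true
#'   prognostic gene IDs, the per-patient linear predictor, and uncensored
#'   event times).
#' @export
simulateTumorCohort <- function(cfg) {
    validateSimConfig(cfg)
    set.seed(.subSeed(cfg$seed, 2L))
    np <- cfg$n_patients
    genes <- .geneIds(cfg$n_genes)
    patients <- sprintf("pt_%04d", seq_len(np))

    age <- .truncNorm(np, 60, 10, 25, 90)
    gender <- ifelse(stats::runif(np) < 0.7, "male", "female")
    t_stage <- sample(1:4, np, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
    n_stage <- sample(0:3, np, replace = TRUE, prob = c(0.4, 0.25, 0.25, 0.1))
    m_stage <- stats::rbinom(np, 1, 0.05)
    hpv <- ifelse(stats::runif(np) < 0.15, "positive", "negative")
    site <- ifelse(stats::runif(np) < 0.25, "TBOT", "other")

    ncand <- cfg$n_ectopic_candidates
    candGenes <- genes[seq_len(ncand)]
    pAct <- rep(cfg$activation_fraction, np)
    if (!is.na(cfg$hpv_activation_fraction))
        pAct[hpv == "positive"] <- cfg$hpv_activation_fraction
    A <- matrix(stats::rbinom(ncand * np, 1, rep(pAct, each = ncand)),
        ncand, np, dimnames = list(candGenes, patients))

    x <- matrix(0, cfg$n_genes, np, dimnames = list(genes, patients))
    nvals <- ncand * np
    bg <- stats::rlnorm(nvals, cfg$background_log_mean, cfg$background_log_sd)
    act <- stats::rlnorm(nvals, cfg$active_log_mean, cfg$active_log_sd)
    x[seq_len(ncand), ] <- ifelse(A == 1, act, bg)
    nbg <- cfg$n_genes - ncand
    if (nbg > 0L) {
        baseline <- stats::runif(nbg, cfg$background_log_mean,
            cfg$active_log_mean)
        x[ncand + seq_len(nbg), ] <- matrix(stats::rlnorm(nbg * np,
            rep(baseline, np), cfg$background_log_sd), nbg, np)
    }

    ntrue <- cfg$n_true_prognostic
    trueGenes <- candGenes[seq_len(ntrue)]
    trueCount <- if (ntrue > 0L)
        colSums(A[trueGenes, , drop = FALSE]) else rep(0, np)

    stageLate <- as.numeric(t_stage >= 3 | n_stage >= 2 | m_stage == 1)
    covDesign <- cbind(
        age = (age - 60) / 10,
        gender = as.numeric(gender == "male"),
        stage_late = stageLate,
        hpv_positive = as.numeric(hpv == "positive"),
        site_tbot = as.numeric(site == "TBOT"))
    eff <- cfg$covariate_effects
    eff <- eff[names(eff) %in% colnames(covDesign)]
    lp <- cfg$log_hazard_per_activation * trueCount +
        if (length(eff)) drop(covDesign[, names(eff), drop = FALSE] %*% eff)
        else 0
    hazard <- cfg$baseline_hazard * exp(lp)

    tEvent <- stats::rexp(np, rate = hazard)
    tDrop <- if (cfg$dropout_rate > 0)
        stats::rexp(np, rate = cfg$dropout_rate) else rep(Inf, np)
    tCens <- pmin(cfg$censor_time, tDrop)
    osMonths <- pmax(pmin(tEvent, tCens), 1e-6)
    event <- as.integer(tEvent <= tCens)

    clinical <- data.frame(patient_id = patients,
        os_months = osMonths, event = event, age = age, gender = gender,
        t_stage = t_stage, n_stage = n_stage, m_stage = m_stage,
        hpv = hpv, site = site,
        grade = sample(c("I", "II", "III"), np, replace = TRUE,
            prob = c(0.3, 0.5, 0.2)),
        stringsAsFactors = FALSE)

    cohort <- TumorCohort(x, clinical)
    list(cohort = cohort,
        truth = list(
            candidate_genes = candGenes,
            true_prognostic_genes = trueGenes,
            activation_matrix = A,
            linear_predictor = stats::setNames(lp, patients),
            event_time = stats::setNames(tEvent, patients)))
}

# staining score distributions for activated vs background marker states
.ihcDrawHigh <- function(n) {
    data.frame(
        intensity = sample(0:3, n, replace = TRUE,
            prob = c(0.03, 0.12, 0.35, 0.50)),
        percent_positive = 100 * stats::rbeta(n, 4, 1.5))
}

.ihcDrawLow <- function(n) {
    data.frame(
        intensity = sample(0:3, n, replace = TRUE,
            prob = c(0.50, 0.30, 0.15, 0.05)),
        percent_positive = 100 * stats::rbeta(n, 1.2, 4))
}

#' Simulate an immunohistochemistry table coupled to activation truth
#'
#' For each patient and marker, staining intensity (0-3) and percent
#' positive tumour cells are drawn from a high-staining distribution with
#' probability \code{ihc_coupling} when the marker is truly activated, and
#' from a low-staining background distribution otherwise. With
#' \code{ihc_coupling = 0} the scores are independent of the truth.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param activationTruth binary markers x patients matrix; rownames are the
#'   marker gene IDs (all requested markers must be present).
#' @param markers marker names to emit (default: all rows of
#'   \code{activationTruth}).
#' @return data.frame with columns \code{patient_id}, \code{marker},
#'   \code{intensity}, \code{percent_positive}.
#' @export
simulateIHCTable <- function(cfg, activationTruth,
        markers = rownames(activationTruth)) {
    validateSimConfig(cfg)
    if (is.null(rownames(activationTruth)))
        stop("activationTruth must have marker rownames", call. = FALSE)
    miss <- setdiff(markers, rownames(activationTruth))
    if (length(miss))
        stop("markers missing from activation truth: ",
            paste(miss, collapse = ", "), call. = FALSE)
    set.seed(.subSeed(cfg$seed, 3L))
    patients <- colnames(activationTruth)
    long <- expand.grid(patient_id = patients, marker = markers,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    act <- activationTruth[cbind(long$marker, long$patient_id)] == 1
    n <- nrow(long)
    useHigh <- act & (stats::runif(n) < cfg$ihc_coupling)
    hi <- .ihcDrawHigh(n)
    lo <- .ihcDrawLow(n)
    long$intensity <- ifelse(useHigh, hi$intensity, lo$intensity)
    long$percent_positive <- ifelse(useHigh, hi$percent_positive,
        lo$percent_positive)
    long
}
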