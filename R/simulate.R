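#' Configuration for a synthetic CUP cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' generator emulates the statistical structure a tissue-of-origin analysis
#' assumes: several tumour classes with class-specific expression signatures,
#' primaries and metastases per class, a group of cancers of unknown primary
#' (CUP) drawn from known classes but with inflated within-class dispersion
#' and an activated chromosomal-instability (CIN) signature, and a pooled
#' normal-tissue group with no tumour signature.
#'
#' Expression is Gaussian on the log2 scale (RMA-like output), with a
#' per-probe baseline drawn once from `N(baseline_mean, baseline_sd^2)`.
#' A sample's class-signature probes are shifted up by `class_effect`;
#' metastases and CUPs (which are modelled as metastases) receive a further
#' `metastasis_effect` on those probes. Instability-signature probes are
#' shifted by `instability_effect` in CUPs and by
#' `met_instability_fraction * instability_effect` in metastases of known
#' origin. CUP noise is `noise_sd * cup_dispersion_factor`.
#'
#' @param n_classes number of tumour classes (>= 1).
#' @param n_probes total number of probes.
#' @param probes_per_class_signature signature probes per class.
#' @param n_primary_per_class,n_metastasis_per_class samples per class.
#' @param n_cup,n_normal cohort-level CUP and normal counts (may be 0).
#' @param class_effect log2 mean shift of a class's signature probes.
#' @param metastasis_effect additional log2 shift in metastases (and CUPs).
#' @param cup_dispersion_factor multiplier (>= 1) on the noise SD of CUPs.
#' @param instability_signature_size number of CIN-signature probes.
#' @param instability_effect log2 up-shift of CIN probes in CUPs.
#' @param met_instability_fraction fraction of `instability_effect` applied to
#'   metastases of known origin (default 0.5: metastases sit between
#'   primaries and CUPs on the instability axis).
#' @param noise_sd per-probe noise SD in log2 units (> 0).
#' @param baseline_mean,baseline_sd per-probe baseline distribution.
#' @param sex_fraction_female probability that a non-sex-restricted sample is
#'   female.
#' @param sex_specific_classes named character vector mapping class labels to
#'   `"F"` or `"M"`; samples of those classes are only generated in the
#'   eligible sex. `NULL` for none.
#' @param seed integer RNG seed.
#'
#' @return A list of class `"cohort_config"`.
#' @seealso [simulate_cohort()], [simulate_gene_sets()]
#' @export
cohort_config <- function(n_classes = 5,
                          n_probes = 1000,
                          probes_per_class_signature = 30,
                          n_primary_per_class = 40,
                          n_metastasis_per_class = 40,
                          n_cup = 40,
                          n_normal = 20,
                          class_effect = 2.0,
                          metastasis_effect = 0.5,
                          cup_dispersion_factor = 2.0,
                          instability_signature_size = 40,
                          instability_effect = 1.0,
                          met_instability_fraction = 0.5,
                          noise_sd = 1.0,
                          baseline_mean = 7.0,
                          baseline_sd = 0.5,
                          sex_fraction_female = 0.5,
                          sex_specific_classes = NULL,
                          seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes),
    n_probes = as.integer(n_probes),
    probes_per_class_signature = as.integer(probes_per_class_signature),
    n_primary_per_class = as.integer(n_primary_per_class),
    n_metastasis_per_class = as.integer(n_metastasis_per_class),
    n_cup = as.integer(n_cup),
    n_normal = as.integer(n_normal),
    class_effect = as.numeric(class_effect),
    metastasis_effect = as.numeric(metastasis_effect),
    cup_dispersion_factor = as.numeric(cup_dispersion_factor),
    instability_signature_size = as.integer(instability_signature_size),
    instability_effect = as.numeric(instability_effect),
    met_instability_fraction = as.numeric(met_instability_fraction),
    noise_sd = as.numeric(noise_sd),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = as.numeric(baseline_sd),
    sex_fraction_female = as.numeric(sex_fraction_female),
    sex_specific_classes = sex_specific_classes,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config a `"cohort_config"` object.
#' @export
validate_cohort_config <- function(config) {
  must_pos <- c("n_classes", "n_probes", "probes_per_class_signature",
                "n_primary_per_class", "n_metastasis_per_class",
                "instability_signature_size")
  for (f in must_pos) {
    if (is.na(config[[f]]) || config[[f]] < 1L)
      stop(sprintf("invalid cohort config: '%s' must be >= 1", f))
  }
  for (f in c("n_cup", "n_normal")) {
    if (is.na(config[[f]]) || config[[f]] < 0L)
      stop(sprintf("invalid cohort config: '%s' must be >= 0", f))
  }
  if (config$cup_dispersion_factor < 1)
    stop("invalid cohort config: 'cup_dispersion_factor' must be >= 1")
  if (config$noise_sd <= 0)
    stop("invalid cohort config: 'noise_sd' must be > 0")
  if (config$baseline_sd < 0)
    stop("invalid cohort config: 'baseline_sd' must be >= 0")
  sig_total <- config$probes_per_class_signature * config$n_classes +
    config$instability_signature_size
  if (sig_total > config$n_probes)
    stop("invalid cohort config: class and instability signatures (",
         sig_total, " probes) exceed 'n_probes' (", config$n_probes, ")")
  if (config$sex_fraction_female < 0 || config$sex_fraction_female > 1)
    stop("invalid cohort config: 'sex_fraction_female' must be in [0, 1]")
  ssc <- config$sex_specific_classes
  if (!is.null(ssc)) {
    labs <- class_labels(config)
    if (is.null(names(ssc)) || !all(names(ssc) %in% labs))
      stop("invalid cohort config: names of 'sex_specific_classes' must be ",
           "class labels (", paste(labs, collapse = ", "), ")")
    if (!all(ssc %in% c("F", "M")))
      stop("invalid cohort config: 'sex_specific_classes' values must be 'F' or 'M'")
  }
  invisible(config)
}

#' @rdname cohort_config
#' @export
class_labels <- function(config) sprintf("C%02d", seq_len(config$n_classes))

# Gene indices for a stratum of probes: most genes have one probe, every third
# gene two, exercising probe -> gene-symbol translation. Gene blocks never
# straddle strata, so signature and null gene pools are disjoint.
.assign_genes <- function(n, gene_offset) {
  out <- integer(n)
  g <- gene_offset
  i <- 1L
  while (i <= n) {
    g <- g + 1L
    k <- if (g %% 3L == 0L && i < n) 2L else 1L
    out[i:(i + k - 1L)] <- g
    i <- i + k
  }
  out
}

#' Simulate a synthetic CUP cohort
#'
#' Draws an expression matrix (probes x samples, log2 scale), a sample table
#' as an analyst would see it (CUP class labels hidden), and a truth table
#' recording every sample's generating class and every probe's role.
#'
#' @param config a [cohort_config()] object.
#' @return A list of class `"cup_cohort"` with elements:
#'   \describe{
#'     \item{expr}{numeric matrix, probes x samples.}
#'     \item{samples}{data frame `sample_id`, `class_label` (`"unknown"` for
#'       CUPs), `group` (primary/metastasis/CUP/normal), `sex`.}
#'     \item{truth}{list with `samples` (true class per sample) and `probes`
#'       (role of every probe: `signature:<class>`, `instability`, `null`).}
#'     \item{annotation}{data frame `probe_id`, `gene_symbol`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cfg <- cohort_config(n_classes = 2, n_probes = 120, n_primary_per_class = 5,
#'                      n_metastasis_per_class = 5, n_cup = 4, n_normal = 2,
#'                      probes_per_class_signature = 10,
#'                      instability_signature_size = 10, seed = 1)
#' coh <- simulate_cohort(cfg)
#' dim(coh$expr)
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    K <- config$n_classes
    labs <- class_labels(config)
    np <- config$n_probes
    psig <- config$probes_per_class_signature
    ncin <- config$instability_signature_size

    probe_id <- sprintf("P%05d", seq_len(np))
    role <- rep("null", np)
    sig_idx <- vector("list", K)
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * psig + 1L):(k * psig)
      sig_idx[[k]] <- idx
      role[idx] <- paste0("signature:", labs[k])
    }
    cin_idx <- (K * psig + 1L):(K * psig + ncin)
    role[cin_idx] <- "instability"

    # gene assignment per stratum so probe pairs never straddle roles
    gene_idx <- integer(np)
    offset <- 0L
    for (r in unique(role)) {
      ii <- which(role == r)
      gene_idx[ii] <- .assign_genes(length(ii), offset)
      offset <- max(gene_idx[ii])
    }
    gene_symbol <- sprintf("G%05d", gene_idx)

    # -- samples ------------------------------------------------------------
    cls <- c(rep(labs, each = config$n_primary_per_class),
             rep(labs, each = config$n_metastasis_per_class),
             rep_len(labs, config$n_cup),
             rep("normal", config$n_normal))
    grp <- c(rep("primary", K * config$n_primary_per_class),
             rep("metastasis", K * config$n_metastasis_per_class),
             rep("CUP", config$n_cup),
             rep("normal", config$n_normal))
    ns <- length(cls)
    sample_id <- sprintf("S%04d", seq_len(ns))

    ssc <- config$sex_specific_classes
    sex <- character(ns)
    for (i in seq_len(ns)) {
      sex[i] <- if (!is.null(ssc) && cls[i] %in% names(ssc)) {
        unname(ssc[cls[i]])
      } else if (stats::runif(1) < config$sex_fraction_female) "F" else "M"
    }

    # -- expression ---------------------------------------------------------
    baseline <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)
    mu <- matrix(baseline, np, ns)
    for (j in seq_len(ns)) {
      k <- match(cls[j], labs)
      if (!is.na(k)) {
        mu[sig_idx[[k]], j] <- mu[sig_idx[[k]], j] + config$class_effect
        if (grp[j] %in% c("metastasis", "CUP"))
          mu[sig_idx[[k]], j] <- mu[sig_idx[[k]], j] + config$metastasis_effect
      }
      if (grp[j] == "CUP") {
        mu[cin_idx, j] <- mu[cin_idx, j] + config$instability_effect
      } else if (grp[j] == "metastasis") {
        mu[cin_idx, j] <- mu[cin_idx, j] +
          config$met_instability_fraction * config$instability_effect
      }
    }
    sd_col <- ifelse(grp == "CUP",
                     config$noise_sd * config$cup_dispersion_factor,
                     config$noise_sd)
    noise <- matrix(stats::rnorm(np * ns), np, ns) *
      rep(sd_col, each = np)
    expr <- mu + noise
    dimnames(expr) <- list(probe_id, sample_id)

    samples <- data.frame(
      sample_id = sample_id,
      class_label = ifelse(grp == "CUP", "unknown", cls),
      group = grp,
      sex = sex,
      stringsAsFactors = FALSE
    )
    truth <- list(
      samples = data.frame(sample_id = sample_id, true_class = cls,
                           group = grp, sex = sex, stringsAsFactors = FALSE),
      probes = data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                          role = role, stringsAsFactors = FALSE)
    )
    annotation <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                             stringsAsFactors = FALSE)
    structure(list(expr = expr, samples = samples, truth = truth,
                   annotation = annotation, config = config),
              class = "cup_cohort")
  })
}

#' @export
print.cup_cohort <- function(x, ...) {
  tab <- table(x$truth$samples$group)
  cat("Synthetic CUP cohort:", nrow(x$expr), "probes x", ncol(x$expr),
      "samples\n")
  cat("  classes:", paste(class_labels(x$config), collapse = ", "), "\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("  probe roles:",
      paste(sprintf("%s=%d", names(table(x$truth$probes$role)),
                    as.integer(table(x$truth$probes$role))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Matched gene-set collection for a synthetic cohort
#'
#' Builds one gene set per class signature, one chromosomal-instability set,
#' and `n_decoys` random decoy sets drawn from the cohort's null genes (genes
#' whose probes carry no simulated effect). Decoys play the role of the bulk
#' of a curated collection: sets unrelated to the planted biology.
#'
#' @param cohort a `"cup_cohort"` object (or its `truth` element).
#' @param n_decoys number of decoy sets.
#' @param decoy_size genes per decoy set; must not exceed the null-gene pool.
#' @param seed integer RNG seed for decoy sampling.
#' @return A named list of character vectors (gene symbols): sets
#'   `SIG_<class>`, `CIN_SIGNATURE`, `DECOY_###`.
#' @export
simulate_gene_sets <- function(cohort, n_decoys = 50, decoy_size = 40,
                               seed = 1L) {
  probes <- if (inherits(cohort, "cup_cohort")) cohort$truth$probes
            else cohort$probes
  if (is.null(probes)) stop("'cohort' must be a cup_cohort or its truth table")
  n_decoys <- as.integer(n_decoys)
  decoy_size <- as.integer(decoy_size)
  if (n_decoys < 0L) stop("'n_decoys' must be >= 0")

  sets <- list()
  sig_roles <- sort(unique(probes$role[startsWith(probes$role, "signature:")]))
  for (r in sig_roles) {
    lab <- sub("^signature:", "", r)
    sets[[paste0("SIG_", lab)]] <-
      sort(unique(probes$gene_symbol[probes$role == r]))
  }
  sets[["CIN_SIGNATURE"]] <-
    sort(unique(probes$gene_symbol[probes$role == "instability"]))

  null_genes <- sort(unique(probes$gene_symbol[probes$role == "null"]))
  if (n_decoys > 0L) {
    if (decoy_size > length(null_genes))
      stop("'decoy_size' (", decoy_size, ") exceeds the null-gene pool (",
           length(null_genes), ")")
    with_seed(seed, {
      for (d in seq_len(n_decoys)) {
        sets[[sprintf("DECOY_%03d", d)]] <-
          sort(sample(null_genes, decoy_size))
      }
    })
  }
  sets
}
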