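#' Parameters for the paired-design expression simulator
#'
#' Defaults mirror the study design the analysis targets: 11 subjects each
#' contributing a placebo and a hapten-challenged biopsy at days 3, 14 and
#' 120, hybridized in date batches, with gene-level residual variances drawn
#' from a scaled inverse chi-square hierarchy (the assumption under which
#' variance moderation is exact).
#'
#' @param n_subjects Number of subjects (paired placebo/treated samples);
#'   must be >= 2.
#' @param n_probes Number of array probes.
#' @param days Integer subset of `c(3, 14, 120)`.
#' @param n_batches Number of hybridization-date batches; subjects are
#'   assigned to batches round-robin so batches stay balanced across
#'   treatment.
#' @param batch_shift_sd SD (log2 units) of per-(batch, probe) additive
#'   shifts.
#' @param subject_intercept_sd SD (log2 units) of per-subject random
#'   intercepts.
#' @param d0,s0_sq Prior degrees of freedom and prior variance of the scaled
#'   inverse chi-square residual-variance hierarchy.
#' @param effect_spec Named list mapping gene-set name to true log2 fold
#'   change, either a single number (all days) or a named vector by day,
#'   e.g. `list(negative = c("3" = 3, "14" = 2, "120" = 1))`. Sets named
#'   here are carved out of the probe pool; remaining probes are background
#'   with zero effect.
#' @param set_fractions Named numeric: fraction of genes assigned to each
#'   effect set (names must match `effect_spec`).
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 11L, n_probes = 2000L,
                       days = c(3L, 14L, 120L), n_batches = 3L,
                       batch_shift_sd = 0.5, subject_intercept_sd = 1.0,
                       d0 = 4, s0_sq = 0.05,
                       effect_spec = effect_spec_dpcp(),
                       set_fractions = c(negative = 0.05, positive = 0.10),
                       seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2 (paired inference)")
  if (!all(days %in% c(3L, 14L, 120L))) stop("days must be within {3, 14, 120}")
  stopifnot(n_probes >= 1L, n_batches >= 1L,
            batch_shift_sd >= 0, subject_intercept_sd >= 0,
            d0 > 0, s0_sq > 0)
  if (!all(names(effect_spec) %in% names(set_fractions)))
    stop("every effect_spec set needs a set_fractions entry")
  for (ef in effect_spec)
    if (!all(is.finite(ef))) stop("effect log2FC must be finite")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_probes = as.integer(n_probes),
                 days = as.integer(days), n_batches = as.integer(n_batches),
                 batch_shift_sd = batch_shift_sd,
                 subject_intercept_sd = subject_intercept_sd,
                 d0 = d0, s0_sq = s0_sq, effect_spec = effect_spec,
                 set_fractions = set_fractions, seed = as.integer(seed)),
            class = "sim_params")
}

#' Hapten-reaction-like effect specification
#'
#' Strong induction of the negative-regulator set at the day-3 peak that
#' decays as the reaction resolves, alongside weaker positive-regulator
#' induction — the signature of a self-limiting delayed-type
#' hypersensitivity response.
#'
#' @return Named list usable as `effect_spec` in [sim_params()].
#' @export
effect_spec_dpcp <- function() {
  list(negative = c("3" = 3, "14" = 2, "120" = 1),
       positive = c("3" = 1, "14" = 0.7, "120" = 0.3))
}

#' Chronic-lesion-like effect specification
#'
#' Strong positive-regulator induction with weak negative-regulator
#' induction — the signature of chronic, unresolved inflammation.
#'
#' @return Named list usable as `effect_spec` in [sim_params()].
#' @export
effect_spec_psoriasis <- function() {
  list(negative = c("3" = 0.5, "14" = 0.5, "120" = 0.5),
       positive = c("3" = 2, "14" = 2, "120" = 2))
}

effect_for_day <- function(ef, day) {
  if (length(ef) == 1L && is.null(names(ef))) return(unname(ef))
  if (as.character(day) %in% names(ef)) return(unname(ef[[as.character(day)]]))
  0
}

#' Simulate a paired placebo/treated expression dataset
#'
#' Generates `value(probe, sample) = baseline + subject intercept +
#' batch shift + treatment effect(day) + noise`, with per-probe residual
#' variances drawn from a scaled inverse chi-square prior. Each subject
#' contributes one placebo and one treated sample per requested day.
#'
#' @param params A `sim_params` object.
#' @return List with elements `matrix` (probes x samples, log2), `design`
#'   (data.frame: sample_id, subject_id, treatment, day, batch), and `truth`
#'   (data.frame: probe_id, gene_symbol, set, true log2FC per day
#'   `lfc_d<day>`, `residual_var`), plus `seed`.
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)

  # genes: most have one probe, some have two (exercises the gene collapse)
  n_genes <- max(1L, ceiling(p$n_probes / 1.25))
  gene_of <- c(seq_len(n_genes),
               sample.int(n_genes, p$n_probes - n_genes, replace = TRUE))
  gene_symbols <- sprintf("G%05d", gene_of)
  probe_ids <- sprintf("p%05d_at", seq_len(p$n_probes))

  # gene-level set assignment, mutually exclusive
  set_names <- names(p$effect_spec)
  gene_set <- rep("background", n_genes)
  cursor <- 0L
  for (sn in set_names) {
    k <- round(p$set_fractions[[sn]] * n_genes)
    if (k > 0L) gene_set[(cursor + 1L):(cursor + k)] <- sn
    cursor <- cursor + k
  }
  probe_set <- gene_set[gene_of]

  baseline <- stats::runif(p$n_probes, 4, 12)
  resid_var <- p$s0_sq * p$d0 / stats::rchisq(p$n_probes, df = p$d0)

  lfc <- matrix(0, p$n_probes, length(p$days),
                dimnames = list(probe_ids, paste0("d", p$days)))
  for (j in seq_along(p$days))
    for (sn in set_names)
      lfc[probe_set == sn, j] <- effect_for_day(p$effect_spec[[sn]], p$days[j])

  subjects <- sprintf("S%02d", seq_len(p$n_subjects))
  batch_of_subject <- rep_len(sprintf("batch%d", seq_len(p$n_batches)),
                              p$n_subjects)
  subj_int <- stats::rnorm(p$n_subjects, 0, p$subject_intercept_sd)
  batch_shift <- matrix(stats::rnorm(p$n_batches * p$n_probes, 0,
                                     p$batch_shift_sd),
                        p$n_probes, p$n_batches,
                        dimnames = list(probe_ids,
                                        sprintf("batch%d",
                                                seq_len(p$n_batches))))

  design <- expand.grid(subject_id = subjects, day = p$days,
                        treatment = c("placebo", "DPCP"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(design$subject_id, design$day, design$treatment), ]
  design$sample_id <- sprintf("%s_d%d_%s", design$subject_id, design$day,
                              design$treatment)
  design$batch <- batch_of_subject[match(design$subject_id, subjects)]
  design <- design[, c("sample_id", "subject_id", "treatment", "day", "batch")]
  rownames(design) <- NULL

  n_samp <- nrow(design)
  mat <- matrix(0, p$n_probes, n_samp,
                dimnames = list(probe_ids, design$sample_id))
  noise_sd <- sqrt(resid_var)
  for (i in seq_len(n_samp)) {
    eff <- if (design$treatment[i] == "DPCP")
      lfc[, paste0("d", design$day[i])] else 0
    mat[, i] <- baseline +
      subj_int[match(design$subject_id[i], subjects)] +
      batch_shift[, design$batch[i]] + eff +
      stats::rnorm(p$n_probes, 0, noise_sd)
  }

  truth <- data.frame(probe_id = probe_ids, gene_symbol = gene_symbols,
                      set = probe_set, stringsAsFactors = FALSE)
  for (j in seq_along(p$days))
    truth[[paste0("lfc_d", p$days[j])]] <- lfc[, j]
  truth$residual_var <- resid_var

  list(matrix = mat, design = design, truth = truth, seed = p$seed)
}

#' Simulate a housekeeping-normalized qPCR table
#'
#' Two groups of samples; the treated group's target Ct sits
#' `true_log2_diff` cycles below the reference group's relative to the
#' housekeeping gene, so its normalized expression `2^-(dCt)` is
#' `2^true_log2_diff`-fold higher in expectation.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param true_log2_diff True log2 expression difference (treated minus
#'   reference).
#' @param noise_sd SD (Ct units) of noise added to the target Ct; must be
#'   >= 0.
#' @param seed Integer seed.
#' @param groups Character vector of two group labels, reference first.
#' @param target_gene Target gene label.
#' @return A qPCR data.frame (columns `sample_id`, `group`, `target_gene`,
#'   `ct_target`, `ct_housekeeping`).
#' @export
simulate_qpcr <- function(n_per_group, true_log2_diff = 0, noise_sd = 0.5,
                          seed = 1L, groups = c("reference", "treated"),
                          target_gene = "TARGET") {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(length(groups) == 2L)
  set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(groups, each = n_per_group)
  hk <- stats::rnorm(n, 20, 0.5)
  dct <- 5 - ifelse(group == groups[2L], true_log2_diff, 0) +
    stats::rnorm(n, 0, noise_sd)
  data.frame(sample_id = sprintf("q%02d", seq_len(n)), group = group,
             target_gene = target_gene, ct_target = hk + dct,
             ct_housekeeping = hk, stringsAsFactors = FALSE)
}

#' Toy ontology and annotations exercising term-closure subtraction
#'
#' Builds a small ontology with two disjoint-rooted families standing in for
#' positive (`GO:0002684`) and negative (`GO:0002683`) regulation of immune
#' system process, each with two child terms, and annotates genes to them.
#' At least one gene is always annotated under both families, so the
#' positive-list subtraction is guaranteed to remove something.
#'
#' @param seed Integer seed for the randomized annotations.
#' @param n_genes Number of randomly annotated genes (besides the guaranteed
#'   dual-family gene).
#' @return List with `graph` (an `ontology_graph`) and `annotations`
#'   (data.frame `gene_symbol`, `term_id`, `evidence`).
#' @export
make_fixture_annotations <- function(seed = 1L, n_genes = 20L) {
  set.seed(seed)
  terms <- c("GO:0002684" = "positive regulation of immune system process",
             "GO:0002683" = "negative regulation of immune system process",
             "GO:0002687" = "positive regulation of leukocyte migration",
             "GO:0002688" = "regulation of leukocyte chemotaxis (positive arm)",
             "GO:0002685" = "negative regulation of leukocyte migration",
             "GO:0002686" = "negative regulation of leukocyte chemotaxis")
  edges <- data.frame(
    child = c("GO:0002687", "GO:0002688", "GO:0002685", "GO:0002686"),
    parent = c("GO:0002684", "GO:0002687", "GO:0002683", "GO:0002685"),
    relation = c("is_a", "is_a", "is_a", "part_of"),
    stringsAsFactors = FALSE)
  graph <- structure(list(terms = terms, edges = edges),
                     class = "ontology_graph")
  pos_terms <- c("GO:0002684", "GO:0002687", "GO:0002688")
  neg_terms <- c("GO:0002683", "GO:0002685", "GO:0002686")
  genes <- sprintf("TG%03d", seq_len(n_genes))
  ann <- data.frame(gene_symbol = character(), term_id = character(),
                    stringsAsFactors = FALSE)
  for (g in genes) {
    fam <- sample(c("pos", "neg", "both"), 1L, prob = c(0.45, 0.45, 0.10))
    tids <- switch(fam,
                   pos = sample(pos_terms, sample(1:2, 1L)),
                   neg = sample(neg_terms, sample(1:2, 1L)),
                   both = c(sample(pos_terms, 1L), sample(neg_terms, 1L)))
    ann <- rbind(ann, data.frame(gene_symbol = g, term_id = tids,
                                 stringsAsFactors = FALSE))
  }
  # guaranteed dual-family annotation
  ann <- rbind(ann,
               data.frame(gene_symbol = "GBOTH",
                          term_id = c("GO:0002688", "GO:0002686"),
                          stringsAsFactors = FALSE))
  ann$evidence <- "IEA"
  ann <- unique(ann)
  rownames(ann) <- NULL
  list(graph = graph, annotations = ann)
}

#' Write a simulated dataset and toy annotation fixtures to a directory
#'
#' Emits `matrix.tsv`, `design.tsv`, `truth.tsv`, `toy.obo`, `toy.gaf` and a
#' `metadata.json` recording the seed.
#'
#' @param sim Output of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @param annotations_seed Seed for [make_fixture_annotations()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, annotations_seed = sim$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$matrix, file.path(dir, "matrix.tsv"))
  write_sample_design(sim$design, file.path(dir, "design.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fx <- make_fixture_annotations(annotations_seed)
  write_obo(fx$graph, file.path(dir, "toy.obo"))
  write_gaf(fx$annotations, file.path(dir, "toy.gaf"))
  jsonlite::write_json(list(seed = sim$seed,
                            n_probes = nrow(sim$matrix),
                            n_samples = ncol(sim$matrix)),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}
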