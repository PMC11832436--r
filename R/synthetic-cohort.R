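#' Default planted expression programs
#'
#' Three programs mirroring the biology the pipeline is built to detect: a
#' stress/regulator program induced in patients with increased index-gene
#' expression, a fibrosis/ECM program induced where it is decreased, and a
#' lipid-handling program repressed there. `effect` is the fold-change
#' multiplier applied in the stated stratum.
#'
#' @param n_genes_per_program Genes per program (default 25).
#' @return data.frame with columns `panel`, `stratum`, `direction`, `effect`,
#'   `size`.
#' @export
default_program_specs <- function(n_genes_per_program = 25L) {
  data.frame(
    panel = c("stress_regulators", "fibrosis_ecm", "lipid_handling"),
    stratum = c("up", "down", "down"),
    direction = c(1L, 1L, -1L),
    effect = c(2.5, 2.2, 2.0),
    size = n_genes_per_program
  )
}

default_covariate_model <- function() {
  # stratum-specific score distributions; the down stratum carries more
  # advanced histology, mirroring the direction (not the values) of real
  # biopsy cohorts
  list(
    steatosis = list(up = c(.15, .35, .35, .15), down = c(.05, .25, .40, .30),
                     unchanged = c(.10, .35, .35, .20)),
    lobular_inflammation = list(up = c(.35, .45, .15, .05),
                                down = c(.10, .35, .35, .20),
                                unchanged = c(.20, .45, .25, .10)),
    ballooning = list(up = c(.45, .35, .20), down = c(.20, .40, .40),
                      unchanged = c(.35, .35, .30)),
    fibrosis = list(up = c(.35, .35, .15, .10, .05),
                    down = c(.10, .25, .25, .25, .15),
                    unchanged = c(.25, .30, .20, .15, .10))
  )
}

#' Simulation configuration for a synthetic biopsy cohort
#'
#' Defines the study conditions the generator emulates: 66 healthy controls
#' versus a patient cohort split into planted index-gene strata of 117 (up),
#' 159 (down) and 120 (unchanged) patients; index-gene fold changes drawn
#' within the observed ranges 1.5 to 21.3 (up) and -1.5 to -7.5 (down);
#' planted expression programs with per-stratum directions; ordinal histology
#' covariates linked to the stratum; and multiplicative log-normal noise.
#'
#' @param n_controls,n_up,n_down,n_unchanged Positive sample counts (defaults
#'   66, 117, 159, 120).
#' @param n_genes Total number of genes (default 1000).
#' @param index_gene Identifier of the stratifying gene (default `"FGF21"`).
#' @param fc_up_range,fc_down_range Signed-FC intervals for the index gene in
#'   up/down patients; must lie within [1.5, Inf) and (-Inf, -1.5].
#' @param fc_unchanged_range Signed-FC interval for unchanged patients,
#'   strictly inside (-threshold, threshold).
#' @param program_specs data.frame as [default_program_specs()].
#' @param noise_sd SD of additive Gaussian noise on the log2 scale (> 0;
#'   default 0.25).
#' @param covariate_model Named list (one entry per score) of per-stratum
#'   category probability vectors; `NULL` disables the stratum link (all
#'   strata share the `unchanged` distribution).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_controls = 66L, n_up = 117L, n_down = 159L,
                       n_unchanged = 120L, n_genes = 1000L,
                       index_gene = "FGF21",
                       fc_up_range = c(1.5, 21.3),
                       fc_down_range = c(-7.5, -1.5),
                       fc_unchanged_range = c(-1.35, 1.35),
                       program_specs = default_program_specs(),
                       noise_sd = 0.25,
                       covariate_model = default_covariate_model(),
                       seed = 1L) {
  counts <- c(n_controls = n_controls, n_up = n_up, n_down = n_down,
              n_unchanged = n_unchanged, n_genes = n_genes)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (fc_up_range[1] < 1.5) stop("fc_up_range must lie within [1.5, Inf)")
  if (fc_down_range[2] > -1.5) stop("fc_down_range must lie within (-Inf, -1.5]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(program_specs)) {
    if (any(!program_specs$stratum %in% c("up", "down", "unchanged")))
      stop("program stratum must be up/down/unchanged")
    if (sum(program_specs$size) > n_genes - 1L)
      stop("program sizes exceed available genes")
    if (any(program_specs$effect < 1))
      stop("program effect is a fold-change multiplier >= 1")
  }
  structure(
    list(n_controls = n_controls, n_up = n_up, n_down = n_down,
         n_unchanged = n_unchanged, n_genes = n_genes,
         index_gene = index_gene, fc_up_range = fc_up_range,
         fc_down_range = fc_down_range,
         fc_unchanged_range = fc_unchanged_range,
         program_specs = program_specs, noise_sd = noise_sd,
         covariate_model = covariate_model, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# signed FC -> log2 ratio (inverse of the reporting convention)
#' @keywords internal
signed_fc_to_log2 <- function(fc) sign(fc) * log2(abs(fc))

# draw signed FCs log-uniformly inside a signed interval
draw_signed_fc <- function(n, range) {
  lo <- signed_fc_to_log2(range[1]); hi <- signed_fc_to_log2(range[2])
  l2 <- stats::runif(n, min(lo, hi), max(lo, hi))
  ifelse(l2 >= 0, 2^l2, -2^(-l2))
}

#' Generate a synthetic stratified cohort
#'
#' Expression is generated on the log2 scale: per-gene control baselines drawn
#' uniformly on log2 [3, 10], planted signed fold changes added as log2
#' ratios for the index gene and program genes of the relevant stratum, and
#' additive Gaussian noise (`noise_sd`), then exponentiated to linear scale.
#' With `noise_sd -> 0` planted fold changes are reproduced exactly. Histology
#' covariates are drawn per stratum from `covariate_model`; controls carry
#' score 0.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (genes x samples matrix), `metadata`
#'   (data.frame in the [read_metadata()] layout) and `truth` (list:
#'   `stratum` named per patient, `index_fc` named per patient, `programs`
#'   data.frame of planted genes with per-stratum direction and effect,
#'   `baselines`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  ng <- config$n_genes
  genes <- sprintf("G%04d", seq_len(ng - 1L))
  genes <- c(config$index_gene, genes)
  if (anyDuplicated(genes)) stop("index_gene collides with generated gene ids")

  n_pat <- config$n_up + config$n_down + config$n_unchanged
  samples <- c(sprintf("CTRL%03d", seq_len(config$n_controls)),
               sprintf("PT%03d", seq_len(n_pat)))
  stratum <- rep(c("up", "down", "unchanged"),
                 c(config$n_up, config$n_down, config$n_unchanged))
  names(stratum) <- samples[-seq_len(config$n_controls)]

  baselines <- stats::runif(ng, 3, 10)
  names(baselines) <- genes

  # planted program membership: disjoint blocks after the index gene
  programs <- NULL
  if (!is.null(config$program_specs) && nrow(config$program_specs) > 0L) {
    spec <- config$program_specs
    need <- sum(spec$size)
    if (need > ng - 1L) stop("program sizes exceed available genes")
    pool <- genes[-1L][seq_len(need)]
    offset <- 0L
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      g <- pool[offset + seq_len(spec$size[i])]
      offset <<- offset + spec$size[i]
      data.frame(gene = g, panel = spec$panel[i], stratum = spec$stratum[i],
                 direction = spec$direction[i], effect = spec$effect[i])
    })
    programs <- do.call(rbind, rows)
  }

  # per-patient index-gene signed FC
  index_fc <- numeric(n_pat)
  index_fc[stratum == "up"] <- draw_signed_fc(config$n_up, config$fc_up_range)
  index_fc[stratum == "down"] <- draw_signed_fc(config$n_down, config$fc_down_range)
  index_fc[stratum == "unchanged"] <-
    draw_signed_fc(config$n_unchanged, config$fc_unchanged_range)
  names(index_fc) <- names(stratum)

  # log2 shift matrix: genes x patients
  shift <- matrix(0, ng, n_pat, dimnames = list(genes, names(stratum)))
  shift[config$index_gene, ] <- signed_fc_to_log2(index_fc)
  if (!is.null(programs)) {
    for (i in seq_len(nrow(programs))) {
      in_str <- stratum == programs$stratum[i]
      shift[programs$gene[i], in_str] <-
        programs$direction[i] * log2(programs$effect[i])
    }
  }

  log2_ctrl <- baselines + matrix(stats::rnorm(ng * config$n_controls,
                                               sd = config$noise_sd),
                                  ng, config$n_controls)
  log2_pat <- baselines + shift + matrix(stats::rnorm(ng * n_pat,
                                                      sd = config$noise_sd),
                                         ng, n_pat)
  expr <- 2^cbind(log2_ctrl, log2_pat)
  dimnames(expr) <- list(genes, samples)

  metadata <- draw_metadata(config, samples, stratum)
  truth <- list(stratum = stratum, index_fc = index_fc, programs = programs,
                baselines = baselines)
  list(expression = expr, metadata = metadata, truth = truth)
}

draw_metadata <- function(config, samples, stratum) {
  n_ctrl <- config$n_controls
  n_pat <- length(stratum)
  cm <- config$covariate_model
  score_of <- function(var, k_max) {
    if (is.null(cm)) return(sample(0:k_max, n_pat, replace = TRUE))
    vapply(stratum, function(s) {
      p <- cm[[var]][[s]]
      sample(seq_along(p) - 1L, 1L, prob = p)
    }, integer(1L))
  }
  st <- score_of("steatosis", 3L)
  li <- score_of("lobular_inflammation", 3L)
  ba <- score_of("ballooning", 2L)
  fi <- score_of("fibrosis", 4L)
  sex <- sample(c("F", "M"), n_ctrl + n_pat, replace = TRUE)
  data.frame(
    sample_id = samples,
    group = rep(c("control", "patient"), c(n_ctrl, n_pat)),
    sex = sex,
    steatosis = c(rep(0L, n_ctrl), st),
    lobular_inflammation = c(rep(0L, n_ctrl), li),
    ballooning = c(rep(0L, n_ctrl), ba),
    nas = c(rep(0L, n_ctrl), st + li + ba),
    fibrosis = c(rep(0L, n_ctrl), fi),
    study_id = "SIM1",
    row.names = NULL
  )
}

#' Generate gene-set fixtures aligned with the planted programs
#'
#' Emits one GMT set per planted program plus, for each, a size-matched decoy
#' set drawn from genes carrying no planted effect — so decoys share no member
#' with any planted differentially expressed gene, by construction.
#'
#' @param config A [sim_config()] with nonempty `program_specs`.
#' @param n_decoys Decoy sets per program (default 1).
#' @return A `gene_set_collection` (category `pathway`).
#' @export
generate_gene_sets <- function(config, n_decoys = 1L) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$program_specs
  if (is.null(spec) || nrow(spec) == 0L) stop("program_specs is empty")
  withr_seed(config$seed + 1L, {
    ng <- config$n_genes
    genes <- c(config$index_gene, sprintf("G%04d", seq_len(ng - 1L)))
    need <- sum(spec$size)
    pool <- genes[-1L][seq_len(need)]          # planted genes, as in generate_cohort
    neutral <- genes[-1L][-seq_len(need)]
    if (max(spec$size) * (1L + n_decoys) > length(neutral) + max(spec$size))
      stop("requested decoy sizes exceed available neutral genes")
    sets <- list(); desc <- character()
    offset <- 0L
    for (i in seq_len(nrow(spec))) {
      nm <- spec$panel[i]
      sets[[nm]] <- pool[offset + seq_len(spec$size[i])]
      desc[nm] <- sprintf("planted program (%s, dir %+d)", spec$stratum[i],
                          spec$direction[i])
      offset <- offset + spec$size[i]
      for (d in seq_len(n_decoys)) {
        if (spec$size[i] > length(neutral))
          stop("decoy size exceeds available neutral genes")
        dn <- sprintf("decoy_%s_%d", nm, d)
        sets[[dn]] <- sample(neutral, spec$size[i])
        desc[dn] <- "decoy set (no planted genes)"
      }
    }
    gene_set_collection(sets, desc, "pathway")
  })
}
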