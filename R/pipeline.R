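#' Pipeline configuration
#'
#' Collects every knob of the full run. Defaults follow the reference
#' design wherever it states one: the 5 x 5 occurrence-threshold grid, 999
#' null replicates, and the "more than 5 networks" frequency rule (i.e.
#' `min_networks = 6`). Input is either a synthetic [sim_config()] or a set
#' of file paths (`fungi`, `bacteria`, `taxonomy`, `metadata`).
#'
#' @param input a [sim_config()] (synthetic run) or a named list of file
#'   paths.
#' @param t_fungal,t_bacterial occurrence-threshold vectors.
#' @param stars a [stars_control()].
#' @param null_replicates random networks per inferred network.
#' @param min_networks frequent-association threshold.
#' @param min_pair_support genus-summary support threshold.
#' @param rule edge-weight symmetrisation rule.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = sim_config(),
                            t_fungal = c(5L, 7L, 9L, 11L, 19L),
                            t_bacterial = c(10L, 20L, 31L, 39L, 46L),
                            stars = stars_control(),
                            null_replicates = 999L,
                            min_networks = 6L,
                            min_pair_support = 2L,
                            rule = "max",
                            seed = 1L) {
  stopifnot(null_replicates >= 1L, min_networks >= 1L)
  structure(list(input = input, t_fungal = t_fungal,
                 t_bacterial = t_bacterial, stars = stars,
                 null_replicates = as.integer(null_replicates),
                 min_networks = as.integer(min_networks),
                 min_pair_support = as.integer(min_pair_support),
                 rule = rule, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; recognised keys mirror the
#'   [pipeline_config()] arguments, with `input` either the string
#'   `"synthetic"` (optionally a mapping of [sim_config()] overrides) or a
#'   mapping of file paths.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  input <- raw$input %||% "synthetic"
  if (identical(input, "synthetic")) {
    input <- sim_config()
  } else if (is.list(input) && is.null(input$fungi)) {
    input <- do.call(sim_config, input)
  }
  args <- raw[setdiff(names(raw), c("input", "stars"))]
  args$input <- input
  if (!is.null(raw$stars)) args$stars <- do.call(stars_control, raw$stars)
  do.call(pipeline_config, args)
}

load_inputs <- function(config) {
  if (inherits(config$input, "sim_config")) {
    sim <- simulate_communities(config$input,
                                seed = derive_seed(config$seed, "simulate"))
    list(fungi = sim$fungi, bacteria = sim$bacteria,
         taxonomy = sim$taxonomy, metadata = sim$metadata,
         truth = sim$truth, simulated = TRUE, sim = sim)
  } else {
    paths <- config$input
    for (k in c("fungi", "bacteria", "metadata")) {
      if (is.null(paths[[k]]) || !file.exists(paths[[k]])) {
        stop("missing input file for '", k, "': ",
             paths[[k]] %||% "<unset>")
      }
    }
    tax <- if (!is.null(paths$taxonomy)) read_taxonomy(paths$taxonomy)
    list(fungi = read_asv_table(paths$fungi, "fungi"),
         bacteria = read_asv_table(paths$bacteria, "bacteria"),
         taxonomy = tax, metadata = read_sample_metadata(paths$metadata),
         truth = NULL, simulated = FALSE)
  }
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the paired tables; community
#' statistics (alpha diversity, PERMANOVA on Bray-Curtis distances, core
#' ASVs and condition-exclusive core, per-phylum richness contrasts);
#' filter-grid network ensemble; per-network properties with the paired
#' condition comparison; random-network null models; frequent-association
#' consensus with genus summaries (and, for synthetic runs, recovery
#' scoring against the planted truth); binomial and Poisson GLMs. All
#' outputs are TSV/JSON files under `output_dir`, inventoried with md5
#' hashes in `manifest.json`. Reruns with the same config and seed are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param output_dir output directory (created if missing).
#' @param progress print stage progress.
#' @return invisibly, a list with the in-memory `results` of every stage
#'   and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- character(0)
  note <- function(...) if (progress) cat(..., "\n")

  note("* inputs")
  inp <- load_inputs(config)
  meta <- inp$metadata
  if (inp$simulated) {
    files <- c(files, write_simulation(inp$sim, file.path(output_dir, "input")))
  }

  note("* community statistics")
  comp <- list()
  for (k in KINGDOMS) {
    tab <- inp[[k]]
    div <- alpha_diversity(tab)
    d <- bray_curtis(relative_abundance(tab))
    m <- aligned_meta(tab, meta)
    perm <- list(
      location = permanova(d, m$location,
                           seed = derive_seed(config$seed, paste0("perm_loc_", k))),
      condition = permanova(d, m$condition,
                            seed = derive_seed(config$seed, paste0("perm_cond_", k))))
    core <- core_asvs(tab, meta)
    excl <- condition_exclusive_core(tab, meta, core)
    rich <- if (!is.null(inp$taxonomy)) {
      phylum_richness_contrast(tab, inp$taxonomy, meta)
    }
    comp[[k]] <- list(diversity = div, permanova = perm, core = core,
                      exclusive = excl, phylum_richness = rich)
    files <- c(files,
               write_tsv(div, file.path(output_dir, paste0("diversity_", k, ".tsv"))),
               write_tsv(excl, file.path(output_dir, paste0("core_exclusive_", k, ".tsv"))))
    if (!is.null(rich)) {
      files <- c(files, write_tsv(rich, file.path(
        output_dir, paste0("phylum_richness_", k, ".tsv"))))
    }
    perm_df <- data.frame(
      factor = names(perm),
      pseudo_F = vapply(perm, `[[`, numeric(1L), "pseudo_F"),
      R2 = vapply(perm, `[[`, numeric(1L), "R2"),
      p = vapply(perm, `[[`, numeric(1L), "p"))
    files <- c(files, write_tsv(perm_df, file.path(
      output_dir, paste0("permanova_", k, ".tsv"))))
  }

  note("* network ensemble (grid)")
  ens <- infer_network_ensemble(
    inp$fungi, inp$bacteria, meta,
    t_fungal = config$t_fungal, t_bacterial = config$t_bacterial,
    control = config$stars, seed = config$seed, rule = config$rule,
    progress = progress)
  net_dir <- file.path(output_dir, "networks")
  if (!dir.exists(net_dir)) dir.create(net_dir)
  for (cond in CONDITIONS) {
    for (net in ens$networks[[cond]]) {
      f <- file.path(net_dir, sprintf("network_%s_tF%02d_tB%02d.tsv",
                                      cond, net$t_fungal, net$t_bacterial))
      files <- c(files, write_network(net, f),
                 sub("\\.tsv$", ".json", f))
    }
  }
  files <- c(files, write_tsv(ens$properties,
                              file.path(output_dir, "network_properties.tsv")))
  comparison <- summary(ens)
  files <- c(files, write_tsv(as.data.frame(comparison),
                              file.path(output_dir, "paired_comparison.tsv")))

  note("* null models")
  nulls <- list(); shared_rows <- list()
  grid <- build_grid(inp$fungi, inp$bacteria, config$t_fungal,
                     config$t_bacterial)
  for (i in seq_along(grid)) {
    fp <- grid[[i]]
    pair_tag <- paste0("tF", fp$t_fungal, "_tB", fp$t_bacterial)
    dataset_nodes <- data.frame(
      id = c(asv_ids(fp$fungi), asv_ids(fp$bacteria)),
      kingdom = rep(KINGDOMS, c(ncol(fp$fungi$counts),
                                ncol(fp$bacteria$counts))),
      stringsAsFactors = FALSE)
    for (cond in CONDITIONS) {
      net <- ens$networks[[cond]][[i]]
      if (nrow(net$edges) == 0L) next
      et <- edge_type_null(net, dataset_nodes, R = config$null_replicates,
                           seed = derive_seed(config$seed,
                                              paste("null", cond, pair_tag)))
      et$network_id <- paste(cond, pair_tag, sep = "_")
      nulls[[length(nulls) + 1L]] <- et
    }
    sf <- ens$networks$snow_free[[i]]; sc <- ens$networks$snow_covered[[i]]
    if (nrow(sf$edges) && nrow(sc$edges)) {
      obs_all <- shared_edges(sf, sc)$n_shared
      obs_fb <- shared_edges(sf, sc, fb_only = TRUE)$n_shared
      sh <- shared_null(dataset_nodes, nrow(sf$edges), dataset_nodes,
                        nrow(sc$edges), R = config$null_replicates,
                        seed = derive_seed(config$seed,
                                           paste("shared", pair_tag)),
                        observed = obs_all)
      shfb <- shared_null(sf$nodes, sum(sf$edges$type == "fb"), sc$nodes,
                          sum(sc$edges$type == "fb"),
                          R = config$null_replicates,
                          seed = derive_seed(config$seed,
                                             paste("sharedfb", pair_tag)),
                          fb_restricted = TRUE, observed = obs_fb)
      shared_rows[[length(shared_rows) + 1L]] <- data.frame(
        t_fungal = fp$t_fungal, t_bacterial = fp$t_bacterial,
        statistic = c("shared_total", "shared_fb"),
        observed = c(obs_all, obs_fb),
        null_mean = c(sh$null_mean, shfb$null_mean),
        null_sd = c(sh$null_sd, shfb$null_sd),
        p_ge = c(sh$p_ge, shfb$p_ge), p_le = c(sh$p_le, shfb$p_le),
        stringsAsFactors = FALSE)
    }
  }
  null_df <- do.call(rbind, c(nulls, list(make.row.names = FALSE)))
  shared_df <- do.call(rbind, c(shared_rows, list(make.row.names = FALSE)))
  files <- c(files, write_tsv(null_df, file.path(output_dir, "null_edge_types.tsv")),
             write_tsv(shared_df, file.path(output_dir, "null_shared.tsv")))

  note("* consensus associations")
  records <- frequent_associations(ens$networks,
                                   min_networks = config$min_networks)
  records <- condition_specificity(records)
  files <- c(files, write_tsv(as.data.frame(records),
                              file.path(output_dir, "frequent_associations.tsv")))
  genus <- recovery <- NULL
  if (!is.null(inp$taxonomy)) {
    genus <- lapply(setNames(nm = CONDITIONS), function(cc) {
      genus_summary(records, inp$taxonomy, cc,
                    min_pair_support = config$min_pair_support)
    })
    for (cc in CONDITIONS) {
      files <- c(files, write_tsv(genus[[cc]], file.path(
        output_dir, paste0("genus_associations_", cc, ".tsv"))))
    }
  }
  if (!is.null(inp$truth)) {
    recovery <- recovery_score(records, inp$truth)
    files <- c(files, write_tsv(recovery,
                                file.path(output_dir, "recovery.tsv")))
  }

  note("* generalized linear models")
  sign_rec <- sign_count_records(ens$networks)
  sign_fit <- tryCatch(fit_sign_binomial(sign_rec), error = function(e) NULL)
  phyl_rec <- phyl_fits <- NULL
  if (!is.null(inp$taxonomy)) {
    phyl_rec <- phylum_freq_records(ens$networks, inp$taxonomy)
    files <- c(files, write_tsv(phyl_rec,
                                file.path(output_dir, "phylum_fb_counts.tsv")))
    keys <- unique(paste(phyl_rec$t_fungal, phyl_rec$t_bacterial))
    phyl_fits <- lapply(setNames(nm = keys), function(key) {
      sub <- phyl_rec[paste(phyl_rec$t_fungal, phyl_rec$t_bacterial) == key, ]
      tryCatch(fit_phylum_poisson(sub), error = function(e) NULL)
    })
    est <- do.call(rbind, c(lapply(keys, function(key) {
      f <- phyl_fits[[key]]
      if (is.null(f)) return(NULL)
      cbind(pair = key, f$estimates)
    }), list(make.row.names = FALSE)))
    if (!is.null(est)) {
      files <- c(files, write_tsv(est, file.path(output_dir,
                                                 "phylum_poisson_estimates.tsv")))
    }
  }
  glm_json <- list(
    binomial = if (!is.null(sign_fit)) list(
      coefficients = as.data.frame(sign_fit$coefficients),
      fitted_odds = as.list(sign_fit$fitted_odds),
      odds_ratio = sign_fit$odds_ratio,
      p_condition = sign_fit$p_condition,
      separation_corrected = sign_fit$separation_corrected),
    poisson_selected_terms = lapply(phyl_fits %||% list(), function(f) {
      if (is.null(f)) NULL else f$selected_terms
    }))
  glm_path <- file.path(output_dir, "glm_models.json")
  jsonlite::write_json(glm_json, glm_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- c(files, glm_path)

  note("* manifest")
  files <- unique(normalizePath(files))
  manifest <- list(
    package = "fbnet",
    version = as.character(packageVersion("fbnet")),
    seed = config$seed,
    config = list(
      t_fungal = config$t_fungal, t_bacterial = config$t_bacterial,
      null_replicates = config$null_replicates,
      min_networks = config$min_networks, rule = config$rule,
      stars = unclass(config$stars),
      synthetic = inherits(config$input, "sim_config")),
    n_filter_pairs = nrow(ens$grid),
    n_networks = 2L * nrow(ens$grid),
    files = data.frame(
      path = sub(paste0("^", normalizePath(output_dir), "/?"), "", files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(
    results = list(inputs = inp, composition = comp, ensemble = ens,
                   comparison = comparison, nulls = null_df,
                   shared_nulls = shared_df, records = records,
                   genus = genus, recovery = recovery,
                   sign_model = sign_fit, phylum_models = phyl_fits),
    manifest = manifest))
}
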