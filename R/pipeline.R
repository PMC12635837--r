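#' Configuration for an analysis pipeline run
#'
#' Bundles everything [run_pipeline()] needs: one or two annotated networks,
#' stage toggles, null-ensemble sizes, a global seed and an output directory.
#' Per-stage seeds are derived from the global seed by a fixed offset per
#' stage, so enabling or disabling one stage never shifts the random stream
#' of another.
#'
#' @param networks named list of networks; each element is either a
#'   `connectome` or a list with `edges` (path), optional `annotations`
#'   (path or named vector), optional `dialect`, `id_col`, `label_col`.
#' @param stages character vector of stages to run, any of `"summary"`,
#'   `"fit"`, `"dcore"`, `"richclub"`, `"composition"`, `"attack"`,
#'   `"typematrix"`.
#' @param n_nulls_rcc,n_nulls_clustering,n_nulls_modularity null-ensemble
#'   sizes.
#' @param n_runs_louvain base runs for consensus community detection.
#' @param seed global integer seed.
#' @param outdir output directory for CSV/JSON artifacts (`NULL` = return
#'   results only, write nothing).
#' @return a `run_config` list.
#' @export
run_config <- function(networks,
                       stages = c("summary", "fit", "dcore", "richclub",
                                  "composition", "attack", "typematrix"),
                       n_nulls_rcc = 100L,
                       n_nulls_clustering = 10L,
                       n_nulls_modularity = 5L,
                       n_runs_louvain = 20L,
                       seed = 1L,
                       outdir = NULL) {
  known <- c("summary", "fit", "dcore", "richclub", "composition",
             "attack", "typematrix")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(names(networks)) || any(names(networks) == ""))
    stop("`networks` must be a named list")
  structure(list(networks = networks, stages = stages,
                 n_nulls_rcc = as.integer(n_nulls_rcc),
                 n_nulls_clustering = as.integer(n_nulls_clustering),
                 n_nulls_modularity = as.integer(n_nulls_modularity),
                 n_runs_louvain = as.integer(n_runs_louvain),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Thin front end over [run_config()]; the YAML mirrors its arguments, with
#' each network given as `edges`/`annotations`/`dialect` paths. Requires the
#' `yaml` package.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

# fixed per-stage seed offsets: adding stages never shifts existing streams
stage_seed <- function(cfg, stage) {
  offsets <- c(summary = 101L, fit = 202L, dcore = 303L, richclub = 404L,
               composition = 505L, attack = 606L, typematrix = 707L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

load_network <- function(spec) {
  if (inherits(spec, "connectome")) return(spec)
  if (!is.list(spec) || is.null(spec$edges))
    stop("each network must be a connectome or a list with an `edges` path")
  dialect <- spec$dialect %||% edge_dialect()
  cc <- read_edge_table(spec$edges, dialect = dialect)
  if (!is.null(spec$annotations)) {
    ann <- if (is.character(spec$annotations) &&
               length(spec$annotations) == 1L &&
               file.exists(spec$annotations)) {
      read_annotations(spec$annotations,
                       id_col = spec$id_col %||% "node_id",
                       label_col = spec$label_col %||% "label")
    } else spec$annotations
    cc <- set_node_types(cc, ann)
  }
  cc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparison pipeline
#'
#' Executes the enabled stages on every configured network: topology summary,
#' in/out degree-distribution fits, D-core matrix with frontier core,
#' normalized rich-club curves with membership and densities, neighbor
#' composition profiles with diversity indices, targeted removal of the
#' frontier core, and the type connectivity matrix with type-level s-cores.
#' A stage failure is caught, recorded under `errors`, and does not abort the
#' remaining stages. When `outdir` is set, every stage writes its CSV/JSON
#' artifact there and a `comparison.csv` lines the networks up side by side.
#'
#' @param cfg a `run_config`.
#' @return (invisibly) a nested list `bundle[[network]][[stage]]`, plus
#'   `comparison` (data frame) and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(config = cfg, networks = list())
  if (!is.null(cfg$outdir) &&
      !dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)

  for (nw in names(cfg$networks)) {
    cc <- load_network(cfg$networks[[nw]])
    res <- list(errors = list())
    run_stage <- function(stage, fn) {
      if (!stage %in% cfg$stages) return(NULL)
      tryCatch(fn(), error = function(e) {
        res$errors[[stage]] <<- conditionMessage(e)
        NULL
      })
    }

    res$summary <- run_stage("summary", function()
      summarize_topology(cc,
                         n_nulls_clustering = cfg$n_nulls_clustering,
                         n_nulls_modularity = cfg$n_nulls_modularity,
                         n_runs_louvain = cfg$n_runs_louvain,
                         seed = stage_seed(cfg, "summary")))

    res$fit <- run_stage("fit", function() {
      lapply(c(`in` = "in", out = "out"), function(dir)
        compare_families(degree_sequence(cc, dir), direction = dir))
    })

    res$dcore <- run_stage("dcore", function() {
      m <- dcore_matrix(cc)
      fr <- frontier_dcores(m)
      list(matrix = m, frontier = fr)
    })

    res$richclub <- run_stage("richclub", function() {
      s <- stage_seed(cfg, "richclub")
      lapply(c(`in` = "in", out = "out"), function(dir) {
        curve <- normalized_rcc(cc, direction = dir,
                                n_nulls = cfg$n_nulls_rcc, seed = s)
        members <- suppressWarnings(
          rc_membership(curve, cc, rule = "above_first_crossing"))
        dens <- if (length(members) >= 2L)
          subgraph_density(cc, members) else NA_real_
        list(curve = curve, members = members, density = dens)
      })
    })

    res$composition <- run_stage("composition", function() {
      core <- res$dcore$frontier$core_nodes %||%
        frontier_dcores(dcore_matrix(cc))$core_nodes
      if (length(core) == 0L) stop("frontier core is empty")
      lapply(c(predecessors = "predecessors", successors = "successors"),
             function(dir) {
               lapply(c(first = 1L, second = 2L), function(ord) {
                 nb <- neighbor_set(cc, core, direction = dir, order = ord)
                 pr <- type_frequencies(nb, cc)
                 list(profile = pr,
                      shannon = shannon_diversity(pr),
                      simpson = simpson_diversity(pr))
               })
             })
    })

    res$attack <- run_stage("attack", function() {
      core <- res$dcore$frontier$core_nodes %||%
        frontier_dcores(dcore_matrix(cc))$core_nodes
      targeted_attack(cc, core)
    })

    res$typematrix <- run_stage("typematrix", function() {
      tm <- type_connectivity_matrix(cc)
      list(matrix = tm,
           score_in = type_score(tm, "in"),
           score_out = type_score(tm, "out"),
           score_all = type_score(tm, "all"))
    })

    out$networks[[nw]] <- res
    if (!is.null(cfg$outdir)) write_stage_files(res, nw, cfg$outdir)
  }

  out$comparison <- comparison_table(out)
  if (!is.null(cfg$outdir)) {
    utils::write.csv(out$comparison,
                     file.path(cfg$outdir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, stages = cfg$stages,
           networks = names(cfg$networks), schema = "connectocore/1"),
      file.path(cfg$outdir, "run_info.json"), auto_unbox = TRUE)
  }
  invisible(out)
}

comparison_table <- function(out) {
  rows <- lapply(names(out$networks), function(nw) {
    res <- out$networks[[nw]]
    s <- res$summary
    core <- res$dcore$frontier$core_nodes
    data.frame(
      network = nw,
      N = s$N %||% NA, E = s$E %||% NA,
      density = s$density %||% NA,
      mean_clustering = s$mean_clustering %||% NA,
      clustering_normalized = s$mean_clustering_normalized %||% NA,
      Q = s$Q %||% NA, Q_normalized = s$Q_normalized %||% NA,
      strongly_connected = s$strongly_connected %||% NA,
      weakly_connected = s$weakly_connected %||% NA,
      degree_strength_spearman = s$degree_strength_spearman %||% NA,
      global_efficiency = s$global_efficiency %||% NA,
      core_size = if (is.null(core)) NA_integer_ else length(core),
      in_weibull_ks = res$fit$`in`$weibull$ks_distance %||% NA,
      in_powerlaw_ks = res$fit$`in`$powerlaw$ks_distance %||% NA,
      attack_clustering_ratio = res$attack$clustering_ratio %||% NA,
      attack_efficiency_ratio = res$attack$efficiency_ratio %||% NA,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_stage_files <- function(res, nw, outdir) {
  pre <- function(name) file.path(outdir, paste0(nw, "_", name))
  if (!is.null(res$summary))
    jsonlite::write_json(unclass(res$summary), pre("summary.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$fit)) {
    fitrep <- lapply(res$fit, function(f)
      list(weibull = unclass(f$weibull), powerlaw = unclass(f$powerlaw),
           loglik_ratio = f$loglik_ratio, preferred_ks = f$preferred_ks,
           preferred_loglik = f$preferred_loglik))
    jsonlite::write_json(fitrep, pre("degree_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$dcore)) {
    utils::write.csv(res$dcore$matrix$sizes, pre("dcore_matrix.csv"))
    utils::write.csv(data.frame(node = res$dcore$frontier$core_nodes),
                     pre("core_nodes.csv"), row.names = FALSE)
  }
  if (!is.null(res$richclub)) {
    for (dir in names(res$richclub)) {
      utils::write.csv(res$richclub[[dir]]$curve,
                       pre(paste0("richclub_", dir, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(res$composition)) {
    div <- do.call(rbind, lapply(names(res$composition), function(dir)
      do.call(rbind, lapply(names(res$composition[[dir]]), function(ord) {
        el <- res$composition[[dir]][[ord]]
        data.frame(direction = dir, order = ord,
                   n_neurons = el$profile$n_neurons,
                   shannon = el$shannon, simpson = el$simpson)
      }))))
    utils::write.csv(div, pre("diversity.csv"), row.names = FALSE)
  }
  if (!is.null(res$attack))
    jsonlite::write_json(res$attack[c("clustering_ratio",
                                      "efficiency_ratio")],
                         pre("attack.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$typematrix))
    utils::write.csv(res$typematrix$matrix$P, pre("type_matrix.csv"))
  invisible(NULL)
}
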