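#' Run the full differential-network analysis pipeline
#'
#' Executes, in order: differential expression (or loading of a
#' precomputed DE table), BH correction and DEG filtering, state
#' discretization, PKN category filtering and DEG restriction, sign
#' resolution, per-phenotype pruning, elementary-circuit enumeration and
#' comparison, differential-regulator identification, exhaustive 1-4-gene
#' perturbation ranking, and (when a GMT collection is supplied)
#' over-representation analysis of the genes up-regulated in the diseased
#' network. All stage outputs plus a run log and a JSON summary are
#' written to `config$out_dir`; identical config and seed give
#' byte-identical outputs.
#'
#' @param config a `pipeline_config`, see [pipeline_config()].
#' @return invisibly, a list with every stage result (`de`, `states`,
#'   `net_disease`, `net_healthy`, `circuits_disease`, `circuits_healthy`,
#'   `circuit_comparison`, `diff_regs`, `candidates`, `ranking`,
#'   `enrichment`, `counts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, hint, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), " (hint: ", hint, ")",
           call. = FALSE)
    })
  }

  stage("config", "check input paths in the config", {
    if (!file.exists(config$pkn)) stop("PKN file not found: ", config$pkn)
    if (!is.null(config$de_table) && !file.exists(config$de_table)) {
      stop("DE table not found: ", config$de_table)
    }
    if (is.null(config$de_table)) {
      for (p in c(config$expression, config$groups)) {
        if (!file.exists(p)) stop("input file not found: ", p)
      }
    }
  })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  de <- stage("dea", "check the expression/group or DE-table input", {
    raw <- if (!is.null(config$de_table)) {
      read_de_table(config$de_table)
    } else {
      expr <- read_expression(config$expression)
      grp <- read_groups(config$groups)
      compute_de(expr, grp, pseudocount = config$pseudocount)
    }
    filter_degs(raw, alpha = config$alpha, lfc_threshold = config$lfc_threshold)
  })
  states <- stage("dea", "DEGs need nonzero fold changes", discretize(de))
  degs <- deg_genes(de)

  nets <- stage("network_inference", "check the 4-column PKN edge file", {
    pkn <- read_network(config$pkn)
    pkn <- filter_categories(pkn, kept = config$kept_categories)
    pkn <- restrict_to_degs(pkn, degs)
    pkn <- resolve_signs(pkn, states)
    net_d <- prune_network(pkn, states, "disease")
    net_h <- prune_network(pkn, states, "healthy")
    audit_network(net_d)
    audit_network(net_h)
    list(d = net_d, h = net_h)
  })

  circ <- stage("circuit_analysis", "lower max_circuit_length on dense networks", {
    cd <- enumerate_circuits(nets$d, max_length = config$max_circuit_length)
    ch <- enumerate_circuits(nets$h, max_length = config$max_circuit_length)
    list(d = cd, h = ch, cmp = compare_circuits(cd, ch))
  })
  dregs <- differential_regulators(nets$d, nets$h)

  candidates <- stage("perturbation_sim", "upstream stages produced no candidates",
                      candidate_genes(nets$d, circ$d, dregs))
  ranking <- stage("perturbation_sim",
                   "shrink the candidate set or raise candidate_cap",
                   rank_combinations(nets$d, states, candidates,
                                     max_combo = config$max_combo,
                                     top_k = config$top_k,
                                     candidate_cap = config$candidate_cap,
                                     step_cap = config$step_cap))

  enr <- NULL
  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", "check the GMT file and the universe", {
      sets <- read_gmt(config$gmt)
      universe <- as.character(de$gene)
      up_net <- intersect(names(nets$d$states), de$gene[de$log2fc > 0])
      enrich(up_net, gene_set_collection(sets, universe), alpha = config$alpha)
    })
  }

  counts <- list(
    n_genes_tested = nrow(de), n_degs = length(degs),
    nodes_disease = length(nets$d$states), edges_disease = nrow(nets$d$edges),
    nodes_healthy = length(nets$h$states), edges_healthy = nrow(nets$h$edges),
    circuits_disease = nrow(circ$d), circuits_healthy = nrow(circ$h),
    circuits_common = nrow(circ$cmp$common),
    n_differential_regulator_targets = length(dregs),
    n_candidates = length(candidates),
    n_combos_evaluated = attr(ranking, "n_evaluated"))

  stage("cli_io", "check that out_dir is writable",
        write_outputs(config, de, states, nets, circ, dregs, candidates,
                      ranking, enr, counts))

  invisible(list(de = de, states = states, net_disease = nets$d,
                 net_healthy = nets$h, circuits_disease = circ$d,
                 circuits_healthy = circ$h, circuit_comparison = circ$cmp,
                 diff_regs = dregs, candidates = candidates, ranking = ranking,
                 enrichment = enr, counts = counts))
}

write_outputs <- function(config, de, states, nets, circ, dregs, candidates,
                          ranking, enr, counts) {
  out <- config$out_dir
  wt <- function(x, file, col.names = TRUE) {
    utils::write.table(x, file.path(out, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  wt(de, "de_table.tsv")
  wt(states, "states.tsv")
  write_network(nets$d$edges, file.path(out, "network_disease.tsv"))
  write_network(nets$h$edges, file.path(out, "network_healthy.tsv"))
  node_states <- states[states$gene %in% union(names(nets$d$states),
                                               names(nets$h$states)), , drop = FALSE]
  node_states$in_disease <- node_states$gene %in% names(nets$d$states)
  node_states$in_healthy <- node_states$gene %in% names(nets$h$states)
  wt(node_states, "node_states.tsv")

  key <- function(tab) paste(tab$nodes, tab$signs, sep = "|")
  common_keys <- key(circ$cmp$common)
  circ_report <- rbind(
    if (nrow(circ$d) > 0) cbind(phenotype = "disease", circ$d,
                                status = ifelse(key(circ$d) %in% common_keys,
                                                "common", "disease_specific")),
    if (nrow(circ$h) > 0) cbind(phenotype = "healthy", circ$h,
                                status = ifelse(key(circ$h) %in% common_keys,
                                                "common", "healthy_specific")))
  if (is.null(circ_report)) {
    circ_report <- data.frame(phenotype = character(0), nodes = character(0),
                              length = integer(0), signs = character(0),
                              n_inhibitions = integer(0), sign = character(0),
                              status = character(0))
  }
  wt(circ_report, "circuits.tsv")

  dreg_tab <- data.frame(
    gene = names(dregs),
    regulators = vapply(dregs, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  wt(dreg_tab, "differential_regulators.tsv")
  wt(ranking, "ranking.tsv")
  if (!is.null(enr)) wt(enr, "enrichment.tsv")

  version <- as.character(utils::packageVersion("dgrnet"))
  params <- config[c("alpha", "lfc_threshold", "kept_categories", "max_combo",
                     "top_k", "max_circuit_length", "candidate_cap",
                     "pseudocount", "step_cap", "seed")]
  summary <- list(tool = "dgrnet", version = version, parameters = params,
                  counts = counts)
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  log_lines <- c(
    sprintf("dgrnet %s run-all", version),
    sprintf("parameters: alpha=%g lfc_threshold=%g max_combo=%d top_k=%g max_circuit_length=%g candidate_cap=%d pseudocount=%g step_cap=%d seed=%d",
            config$alpha, config$lfc_threshold, config$max_combo, config$top_k,
            config$max_circuit_length, config$candidate_cap, config$pseudocount,
            config$step_cap, config$seed),
    sprintf("kept categories: %s", paste(config$kept_categories, collapse = ", ")),
    sprintf("DEGs: %d of %d genes tested", counts$n_degs, counts$n_genes_tested),
    sprintf("disease network: %d genes, %d interactions",
            counts$nodes_disease, counts$edges_disease),
    sprintf("healthy network: %d genes, %d interactions",
            counts$nodes_healthy, counts$edges_healthy),
    sprintf("elementary circuits: %d disease, %d healthy, %d common",
            counts$circuits_disease, counts$circuits_healthy,
            counts$circuits_common),
    sprintf("perturbation candidates: %d; combinations evaluated: %d",
            counts$n_candidates, counts$n_combos_evaluated),
    "top-ranked perturbations:",
    if (nrow(ranking) > 0) {
      sprintf("  %d. {%s} score=%d baseline=%d", ranking$rank, ranking$genes,
              ranking$score, ranking$baseline_score)
    } else "  (none)")
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(NULL)
}
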