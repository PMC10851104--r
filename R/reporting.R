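# Tabulated reports and the pipeline configuration surface.

#' Default pipeline configuration
#'
#' Single source for the pipeline thresholds: contact cutoff (5 A), hub MCC
#' threshold (4), tumor-mutation-burden cutoff (10 mutations/Mb), recurrence
#' minimum (3 samples), per-class mean-ddG thresholds (1.0 kcal/mol for
#' histone-DNA, 1.5 for histone-histone and histone-partner) and the
#' interface-redundancy Jaccard (0.8).
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(cutoff = 5.0,
       mcc_threshold = 4,
       tmb_cutoff = 10.0,
       recurrence_min = 3,
       ddg_thresholds = c(HDI = 1.0, HHI = 1.5, HPI = 1.5),
       redundancy_jaccard = 0.8,
       callable_mb = 38)
}

#' Load a pipeline configuration from YAML
#'
#' Values absent from the file fall back to [default_config()].
#' @param path YAML file (or NULL for defaults).
#' @return named list of parameters.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (nm in names(user)) {
    if (nm == "ddg_thresholds") {
      cfg$ddg_thresholds[names(user[[nm]])] <- unlist(user[[nm]])
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Tabulate interactions per class (and organism)
#'
#' @param edges interface edge table.
#' @return data.frame: interaction class x organism counts (organism column
#'   omitted when absent).
#' @export
report_interactions <- function(edges) {
  keep <- edges$class %in% c("HHI", "HDI", "HPI", "DPI")
  ed <- edges[keep, , drop = FALSE]
  if (!is.null(ed$organism) && any(!is.na(ed$organism))) {
    org <- ifelse(is.na(ed$organism), "unknown", ed$organism)
    tab <- as.data.frame(table(class = ed$class, organism = org),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    return(tab[tab$n > 0, , drop = FALSE])
  }
  tab <- as.data.frame(table(class = ed$class), stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab
}

#' Tabulate binding partners per functional class
#'
#' @param partner_ids character vector of partner molecule ids.
#' @param annotations data.frame (partner_id or structure_id, class).
#' @param by name of the id column in `annotations`.
#' @return data.frame: class, n_partners (descending), unannotated partners
#'   grouped as "unclassified".
#' @export
report_partners_by_function <- function(partner_ids, annotations,
                                        by = "partner_id") {
  cls <- annotations$class[match(partner_ids, annotations[[by]])]
  cls[is.na(cls)] <- "unclassified"
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(class = names(tab), n_partners = as.integer(tab),
             stringsAsFactors = FALSE)
}

# run log shared by the CLI subcommands
.write_run_log <- function(out_dir, subcommand, params, seed) {
  log <- list(tool = "histonet",
              version = as.character(utils::packageVersion("histonet")),
              r_version = as.character(getRversion()),
              subcommand = subcommand,
              seed = seed,
              params = params,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, file.path(out_dir,
                                      paste0("run_", subcommand, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
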