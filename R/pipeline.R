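# Pipeline configuration, report writers and the subcommand dispatcher
# behind the command-line wrapper (inst/cli/braftools.R).

# Atomic TSV/JSON writers with a provenance header (tool version + config
# hash); outputs contain no timestamps so identical inputs reproduce
# byte-identical files.
.provenance <- function(config_hash = NA_character_) {
  sprintf("# braftools %s%s",
          as.character(utils::packageVersion("braftools")),
          if (is.na(config_hash)) "" else paste0(" config:", config_hash))
}

.write_tsv <- function(df, file, config_hash = NA_character_) {
  tmp <- paste0(file, ".tmp")
  con <- file(tmp, open = "wt")
  writeLines(.provenance(config_hash), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  file.rename(tmp, file)
  invisible(file)
}

.write_json <- function(x, file, config_hash = NA_character_) {
  tmp <- paste0(file, ".tmp")
  x$provenance <- .provenance(config_hash)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, file)
  invisible(file)
}

#' Pipeline configuration
#'
#' All numeric settings of the analysis, with defaults equal to the
#' standard cutoffs used throughout the package: alpha-C boundary 19.6 A,
#' DFG boundary 140 deg, salt bridge 4.0 A (NZ-carboxylate) and 4.5 A
#' (minimum sidechain), h-bond 3.5 A, hydrophobic 4.0/4.5 A
#' (aromatic/non-aromatic), contact 4.5 A, stable-contact threshold 0.7,
#' classifier threshold 0.3 A, trim fraction 0.4, 50 histogram bins, 4
#' communities.
#'
#' @param file Optional flat `key = value` config file (one setting per
#'   line, `#` comments allowed); values given there override defaults, and
#'   explicit arguments override the file.
#' @param ... Named overrides of individual settings.
#' @return A validated `run_config` list.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    alpha_c_boundary = 19.6, dfg_cutoff = 140,
    sb_cutoff = 4.0, sb_sidechain_cutoff = 4.5,
    hbond_cutoff = 3.5, aromatic_cutoff = 4.0, nonaromatic_cutoff = 4.5,
    contact_cutoff = 4.5, stability_threshold = 0.7,
    classifier_threshold = 0.3, trim_fraction = 0.4,
    n_bins = 50, n_communities = 4, seed = 1L)
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      val <- gsub('^"|"$', "", val)
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (is.na(num)) val else num
    }
  }
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  .validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

.validate_config <- function(cfg) {
  pos <- c("alpha_c_boundary", "dfg_cutoff", "sb_cutoff",
           "sb_sidechain_cutoff", "hbond_cutoff", "aromatic_cutoff",
           "nonaromatic_cutoff", "contact_cutoff", "classifier_threshold")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config validation failure: ", k, " must be a positive number")
  }
  if (cfg$stability_threshold < 0 || cfg$stability_threshold > 1)
    stop("config validation failure: stability_threshold must lie in [0, 1]")
  if (cfg$trim_fraction < 0 || cfg$trim_fraction >= 1)
    stop("config validation failure: trim_fraction must lie in [0, 1)")
  if (cfg$n_bins < 1 || cfg$n_communities < 1)
    stop("config validation failure: n_bins and n_communities must be >= 1")
  invisible(cfg)
}

.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                ""), sep = "=", collapse = ";")
  # small stable polynomial hash; enough for provenance tagging
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run one pipeline stage
#'
#' Subcommand dispatcher used by the CLI wrapper: `descriptors` (TSV of
#' per-protomer descriptors for one or more structure files), `fingerprint`
#' (fingerprint TSV + flag JSON for a structure/ligand), `classify`
#' (selectivity-call JSON, or a batch TSV over a directory), `trajseries`
#' (per-frame descriptor TSV from a trajectory), `dcna` (difference contact
#' network JSON/GraphML from an apo and a holo trajectory), and `synth`
#' (write a synthetic demonstration structure and trajectory).
#'
#' @param config A `run_config`.
#' @param command One of `"descriptors"`, `"fingerprint"`, `"classify"`,
#'   `"trajseries"`, `"dcna"`, `"synth"`.
#' @param inputs Named list of command inputs: `structure` (path or paths),
#'   `ligand` (het-code), `trajectory`/`apo`/`holo` (paths), `topology`
#'   (path), `directory` (batch classify).
#' @param out_prefix Prefix for output files.
#' @param quiet Suppress progress messages to stderr.
#' @return (Invisibly) a list of written file paths.
#' @export
run_pipeline <- function(config, command, inputs = list(),
                         out_prefix = "braftools_out", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config)
  log <- function(...) if (!quiet) message("[braftools ", command, "] ", ...)
  need <- function(key) {
    if (is.null(inputs[[key]]))
      stop("missing input '", key, "' for command ", command)
    inputs[[key]]
  }
  log("config hash ", hash)
  written <- character()
  t0 <- proc.time()[["elapsed"]]

  if (command == "descriptors") {
    paths <- need("structure")
    structs <- lapply(paths, read_structure)
    f <- paste0(out_prefix, "_descriptors.tsv")
    descriptor_table(structs, file = f,
                     alpha_c_boundary = config$alpha_c_boundary,
                     dfg_cutoff = config$dfg_cutoff,
                     sb_cutoff = config$sb_cutoff,
                     sb_sidechain_cutoff = config$sb_sidechain_cutoff)
    written <- f
  } else if (command == "fingerprint") {
    s <- read_structure(need("structure"))
    het <- need("ligand")
    ligs <- Filter(function(l) l$res_name == het, s$ligands)
    if (!length(ligs)) stop("ligand ", het, " not found in structure")
    for (l in ligs) {
      fp <- build_fingerprint(protomer_atoms(s, l$chain), l,
                              hbond_cutoff = config$hbond_cutoff,
                              aromatic_cutoff = config$aromatic_cutoff,
                              nonaromatic_cutoff = config$nonaromatic_cutoff)
      f_tsv <- sprintf("%s_fingerprint_%s_%s.tsv", out_prefix, het, l$chain)
      f_json <- sprintf("%s_fingerprint_%s_%s.json", out_prefix, het, l$chain)
      write_fingerprint(fp, f_tsv, json = f_json)
      written <- c(written, f_tsv, f_json)
    }
  } else if (command == "classify") {
    if (!is.null(inputs$directory)) {
      files <- sort(list.files(inputs$directory, pattern = "\\.(pdb|cif)$",
                               full.names = TRUE))
      rows <- lapply(files, function(p) {
        call <- tryCatch(
          classify_structure(read_structure(p), need("ligand"),
                             threshold = config$classifier_threshold),
          error = function(e) NULL)
        if (is.null(call)) return(NULL)
        data.frame(structure = basename(p), label = call$label,
                   glu501_hbond = call$glu501_hbond,
                   delta_alpha_c = call$delta_alpha_c_rounded,
                   delta_ke = call$delta_ke_rounded)
      })
      f <- paste0(out_prefix, "_classify.tsv")
      .write_tsv(do.call(rbind, rows), f, hash)
      written <- f
    } else {
      s <- read_structure(need("structure"))
      call <- classify_structure(s, need("ligand"),
                                 threshold = config$classifier_threshold)
      f <- paste0(out_prefix, "_classify.json")
      .write_json(list(label = call$label, glu501_hbond = call$glu501_hbond,
                       delta_alpha_c = call$delta_alpha_c,
                       delta_ke = call$delta_ke,
                       threshold = call$threshold,
                       evidence_notes = call$evidence_notes), f, hash)
      written <- f
    }
  } else if (command == "trajseries") {
    topo <- if (!is.null(inputs$topology)) read_structure(inputs$topology)
    traj <- read_trajectory(need("trajectory"), topology = topo)
    series <- extract_series(traj, trim_fraction = config$trim_fraction)
    for (s in series) {
      f <- sprintf("%s_series_%s.tsv", out_prefix, s$protomer_id)
      .write_tsv(s$frames, f, hash)
      written <- c(written, f)
    }
  } else if (command == "dcna") {
    topo <- if (!is.null(inputs$topology)) read_structure(inputs$topology)
    apo <- read_trajectory(need("apo"), topology = topo)
    holo <- read_trajectory(need("holo"), topology = topo)
    cm_apo <- contact_probabilities(apo, cutoff = config$contact_cutoff)
    cm_holo <- contact_probabilities(holo, cutoff = config$contact_cutoff)
    g <- stable_contact_graph(cm_apo, threshold = config$stability_threshold)
    part <- detect_communities(g, k = config$n_communities)
    protomer_of <- community_protomers(part)
    dn <- diff_network(community_average_contacts(cm_holo, part),
                       community_average_contacts(cm_apo, part),
                       protomer_of)
    f_json <- paste0(out_prefix, "_dcna.json")
    f_gml <- paste0(out_prefix, "_dcna.graphml")
    write_diff_network(dn, f_json, graphml = f_gml)
    written <- c(f_json, f_gml)
  } else if (command == "synth") {
    spec <- synthetic_spec(seed = config$seed)
    f_pdb <- paste0(out_prefix, "_synthetic.pdb")
    write_structure(make_structure(.static_spec(spec)), f_pdb)
    traj <- make_trajectory(synthetic_spec(seed = config$seed,
                                           n_frames = 200L, n_replicas = 1L))
    f_traj <- paste0(out_prefix, "_synthetic_traj.pdb")
    write_trajectory_pdb(traj[[1]], f_traj)
    written <- c(f_pdb, f_traj)
  } else {
    stop("unknown command: ", command)
  }
  log(sprintf("done in %.2f s; wrote: %s",
              proc.time()[["elapsed"]] - t0, paste(written, collapse = ", ")))
  invisible(list(files = written, config_hash = hash))
}
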