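# Orchestration: run the full analysis (geometry vs B-form reference,
# contacts, superposition panel, phosphate path, coordination shell) from a
# single validated configuration, emitting a reproducible report bundle.

#' Build and validate an analysis configuration
#'
#' @param complex path to the protein-DNA complex structure (or a
#'   `structure3d`).
#' @param apo_ion optional path/structure of the metal-bound apo enzyme.
#' @param strand1,strand2 DNA chain ids (strand 1 = cleaved strand).
#' @param scissile `c(chain, resseq)` of the +1 nucleotide, or NULL.
#' @param outdir output directory for the report bundle.
#' @param polar_cutoff,vdw_cutoff contact cutoffs (A).
#' @param groove_offset,refined_grooves groove-width convention.
#' @param shell_cutoff Mg coordination cutoff (A).
#' @param distance_queries optional list of `c(spec1, spec2)` atom-spec
#'   pairs for the distance panel.
#' @param seed integer seed recorded in the run log.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(complex, apo_ion = NULL, strand1 = "A",
                            strand2 = NULL, scissile = NULL,
                            outdir = tempfile("nickscope_run_"),
                            polar_cutoff = 3.5, vdw_cutoff = 4.0,
                            groove_offset = 2, refined_grooves = FALSE,
                            shell_cutoff = 2.6, distance_queries = NULL,
                            seed = 20210923) {
  load_s <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "structure3d")) return(x)
    if (!file.exists(x)) stop("config: ", what, " file not found: ", x)
    read_structure(x)
  }
  cfg <- list(complex = load_s(complex, "complex"),
              apo_ion = load_s(apo_ion, "apo_ion"),
              strand1 = strand1, strand2 = strand2, scissile = scissile,
              outdir = outdir, polar_cutoff = polar_cutoff,
              vdw_cutoff = vdw_cutoff, groove_offset = groove_offset,
              refined_grooves = refined_grooves,
              shell_cutoff = shell_cutoff,
              distance_queries = distance_queries, seed = as.integer(seed))
  chains <- unique(cfg$complex$atoms$chain)
  if (!strand1 %in% chains)
    stop("config: strand1 chain '", strand1, "' absent from complex")
  if (!is.null(strand2) && !strand2 %in% chains)
    stop("config: strand2 chain '", strand2, "' absent from complex")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Recognised keys: complex, apo_ion, strand1, strand2, scissile_chain,
#' scissile_resseq, outdir, polar_cutoff, vdw_cutoff, groove_offset,
#' refined_grooves, shell_cutoff, seed. Lines starting with '#' are
#' comments.
#'
#' @param path config file path.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(k, default = NULL) if (k %in% keys) vals[keys == k][1]
  else default
  num <- function(k, default) as.numeric(get(k, default))
  sc <- if (!is.null(get("scissile_chain")))
    c(get("scissile_chain"), get("scissile_resseq")) else NULL
  analysis_config(
    complex = get("complex"), apo_ion = get("apo_ion"),
    strand1 = get("strand1", "A"), strand2 = get("strand2"),
    scissile = sc, outdir = get("outdir", tempfile("nickscope_run_")),
    polar_cutoff = num("polar_cutoff", 3.5),
    vdw_cutoff = num("vdw_cutoff", 4.0),
    groove_offset = num("groove_offset", 2),
    refined_grooves = identical(get("refined_grooves", "false"), "true"),
    shell_cutoff = num("shell_cutoff", 2.6),
    seed = num("seed", 20210923))
}

#' Run the full analysis pipeline
#'
#' Stages: relative numbering -> geometry profile + matching canonical
#' B-form reference + deltas -> protein-DNA contacts -> superposition panel
#' (if an apo+ion structure is given) -> scissile-phosphate path (if the
#' complex carries two phosphate conformers as altlocs A/B) -> ion
#' coordination shell -> distance panel. Stage failures are logged and
#' independent stages still run.
#'
#' @param cfg an [analysis_config()].
#' @return object of class `report_bundle`: named list of stage results,
#'   `files` written under `cfg$outdir`, and `log`.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    invisible(NULL)
  }
  bundle <- list()
  files <- character()
  s <- cfg$complex
  if (!is.null(cfg$scissile)) {
    s <- tryCatch(assign_relative_numbering(s, cfg$scissile),
                  error = function(e) {
                    note("stage numbering FAILED: ", conditionMessage(e))
                    s
                  })
  }
  note("stage numbering: scissile = ",
       if (is.null(cfg$scissile)) "none" else
         paste(cfg$scissile, collapse = ":"))
  # geometry + reference
  bundle$geometry <- tryCatch({
    gp <- geometry_profile(s, cfg$strand1, cfg$strand2,
                           groove_offset = cfg$groove_offset,
                           refined_grooves = cfg$refined_grooves)
    seq1 <- gsub("^D", "", gp$resname1)
    ref_s <- build_duplex(duplex_spec(paste(seq1, collapse = "")))
    if (!is.null(cfg$scissile) && !anyNA(gp$position)) {
      plus1 <- which(gp$position == 1)
      if (length(plus1))
        ref_s <- assign_relative_numbering(ref_s, c("A", plus1))
    }
    ref <- geometry_profile(ref_s, "A", "B",
                            groove_offset = cfg$groove_offset,
                            refined_grooves = cfg$refined_grooves)
    ref$position <- gp$position
    cmp <- compare_profiles(gp, ref)
    f1 <- file.path(cfg$outdir, "geometry.tsv")
    utils::write.table(as.data.frame(gp), f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- file.path(cfg$outdir, "geometry_reference.tsv")
    utils::write.table(as.data.frame(ref), f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f3 <- file.path(cfg$outdir, "geometry_deltas.tsv")
    utils::write.table(cmp$deltas, f3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f1, f2, f3)
    note("stage geometry: ", nrow(gp), " pairs; groove_offset=",
         cfg$groove_offset, " refined=", cfg$refined_grooves)
    list(profile = gp, reference = ref, comparison = cmp)
  }, error = function(e) {
    note("stage geometry FAILED: ", conditionMessage(e))
    NULL
  })
  # contacts
  bundle$contacts <- tryCatch({
    ct <- find_contacts(s, cfg$polar_cutoff, cfg$vdw_cutoff)
    f <- file.path(cfg$outdir, "contacts.tsv")
    contact_report(ct, f, "tsv")
    files <- c(files, f)
    note("stage contacts: ", nrow(ct), " records (polar<=",
         cfg$polar_cutoff, ", vdw<=", cfg$vdw_cutoff, ")")
    ct
  }, error = function(e) {
    note("stage contacts SKIPPED: ", conditionMessage(e))
    NULL
  })
  # superposition panel
  bundle$superposition <- tryCatch({
    if (is.null(cfg$apo_ion)) {
      note("stage superposition SKIPPED: no apo_ion structure")
      NULL
    } else {
      sp <- superpose(cfg$apo_ion, s, "calpha")
      panel <- list(calpha_rmsd = sp$rmsd, n_atoms = sp$n_atoms,
                    selection = "calpha")
      f <- file.path(cfg$outdir, "superposition.json")
      jsonlite::write_json(panel, f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
      note("stage superposition: calpha rmsd = ",
           format(sp$rmsd, digits = 4), " over ", sp$n_atoms, " atoms")
      c(panel, list(superposed = sp$mobile))
    }
  }, error = function(e) {
    note("stage superposition FAILED: ", conditionMessage(e))
    NULL
  })
  # phosphate path between altloc conformers
  bundle$path <- tryCatch({
    plus1 <- NULL
    if (!is.null(cfg$scissile)) plus1 <- cfg$scissile
    has_alt <- !is.null(plus1) &&
      any(s$atoms$chain == plus1[1] &
            s$atoms$resseq == as.integer(plus1[2]) &
            s$atoms$name == "P" & s$atoms$altloc == "B")
    if (!has_alt) {
      note("stage path SKIPPED: no two-conformer scissile phosphate")
      NULL
    } else {
      sA <- resolve_altlocs(s, "label:A")
      sB <- resolve_altlocs(s, "label:B")
      path <- torsion_drive(sA, sB, plus1, n_steps = 100)
      ps <- path_to_structure(path)
      f1 <- file.path(cfg$outdir, "path.pdb")
      write_structure(ps, f1, multi_model = TRUE)
      f2 <- file.path(cfg$outdir, "path.tsv")
      utils::write.table(path$driven, f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f1, f2)
      note("stage path: ", path$n_steps + 1, " frames")
      path
    }
  }, error = function(e) {
    note("stage path FAILED: ", conditionMessage(e))
    NULL
  })
  # coordination shell
  bundle$shell <- tryCatch({
    ions <- ion_atoms(if (!is.null(bundle$superposition) &&
                            !is.null(bundle$superposition$superposed))
      bundle$superposition$superposed else
        if (!is.null(cfg$apo_ion)) cfg$apo_ion else s)
    if (!nrow(ions)) {
      note("stage shell SKIPPED: no metal ion present")
      NULL
    } else {
      src <- if (!is.null(bundle$superposition) &&
                   !is.null(bundle$superposition$superposed))
        bundle$superposition$superposed else
          if (!is.null(cfg$apo_ion)) cfg$apo_ion else s
      sh <- coordination_shell(src, ions[1, , drop = FALSE],
                               cutoff = cfg$shell_cutoff)
      f <- file.path(cfg$outdir, "coordination.json")
      jsonlite::write_json(list(
        coordination_number = sh$coordination_number,
        octahedricity = sh$octahedricity,
        sub_octahedral = sh$sub_octahedral,
        ligands = sh$ligands), f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
      note("stage shell: coordination number ", sh$coordination_number)
      sh
    }
  }, error = function(e) {
    note("stage shell FAILED: ", conditionMessage(e))
    NULL
  })
  # distance panel
  bundle$distances <- tryCatch({
    if (is.null(cfg$distance_queries)) {
      note("stage distances SKIPPED: no queries")
      NULL
    } else {
      dp <- distance_panel(s, cfg$distance_queries)
      f <- file.path(cfg$outdir, "distances.tsv")
      utils::write.table(dp, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
      note("stage distances: ", nrow(dp), " queries")
      dp
    }
  }, error = function(e) {
    note("stage distances FAILED: ", conditionMessage(e))
    NULL
  })
  logfile <- file.path(cfg$outdir, "run.log")
  writeLines(c(sprintf("nickscope run; seed=%d", cfg$seed), log), logfile)
  out <- list(stages = bundle, files = files, log = log,
              outdir = cfg$outdir)
  class(out) <- "report_bundle"
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle in", x$outdir, "\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Distances between named atom pairs
#'
#' @param s a `structure3d` (or the `mobile` element of a [superpose()]
#'   result together with its reference merged into one structure).
#' @param queries list of `c(spec1, spec2)` atom-spec pairs; specs may be
#'   altloc-qualified ("A:+1:OP2:B") or label-based ("MG", "W5").
#' @return data.frame with one row per query: both specs, resolved atom
#'   provenance, distance in Angstrom.
#' @export
distance_panel <- function(s, queries) {
  rows <- lapply(queries, function(q) {
    a1 <- resolve_atom(s, q[1]); a2 <- resolve_atom(s, q[2])
    data.frame(spec1 = q[1], spec2 = q[2],
               atom1 = sprintf("%s:%s%d:%s%s", a1$chain, a1$resname,
                               a1$resseq, a1$name,
                               ifelse(nzchar(a1$altloc),
                                      paste0(":", a1$altloc), "")),
               atom2 = sprintf("%s:%s%d:%s%s", a2$chain, a2$resname,
                               a2$resseq, a2$name,
                               ifelse(nzchar(a2$altloc),
                                      paste0(":", a2$altloc), "")),
               distance = vnorm(atom_xyz(a1) - atom_xyz(a2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
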