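# Readers and writers: CIF structure export, JSONL record and trajectory
# streams.  JSONL (one record per line) keeps Monte Carlo archives
# streamable and diffable; energies are serialized at full double
# precision.

.SCHEMA <- "evccp/1"

#' Write a polymorph record to CIF
#'
#' Exports the full unit cell (P1-expanded, fractional coordinates in
#' [0, 1)).
#'
#' @param record A `polymorph_record`.
#' @param mol,sg As in [expand_to_cell()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cif <- function(record, mol, sg, path) {
  st <- record$state
  ex <- expand_to_cell(st, mol, sg)
  frac <- ex$frac %% 1
  name <- record$provenance$run %||% "evccp"
  id <- record$provenance$trial %||% record$provenance$iter %||% 1
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("data_%s_%s", gsub("[^A-Za-z0-9_]", "_", name), as.character(id))
  wl("_symmetry_space_group_name_H-M   'P 1'")
  wl("_symmetry_Int_Tables_number      1")
  wl("_cell_length_a    %.6f", st$cell[1])
  wl("_cell_length_b    %.6f", st$cell[2])
  wl("_cell_length_c    %.6f", st$cell[3])
  wl("_cell_angle_alpha %.6f", st$cell[4])
  wl("_cell_angle_beta  %.6f", st$cell[5])
  wl("_cell_angle_gamma %.6f", st$cell[6])
  wl("loop_")
  wl("_atom_site_label")
  wl("_atom_site_type_symbol")
  wl("_atom_site_fract_x")
  wl("_atom_site_fract_y")
  wl("_atom_site_fract_z")
  for (i in seq_len(nrow(frac))) {
    wl("X%d_%d_%d C %.6f %.6f %.6f", ex$op_id[i], ex$mol_id[i],
       ex$site_id[i], frac[i, 1], frac[i, 2], frac[i, 3])
  }
  invisible(path)
}

#' Read a CIF file written by [write_cif()]
#'
#' Minimal parser for the subset emitted by this package: cell parameters
#' and the P1 fractional atom-site loop.
#'
#' @param path CIF file.
#' @return List with `cell` (length 6), `frac` (n x 3), `labels`.
#' @export
read_cif <- function(path) {
  lines <- readLines(path)
  getnum <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(ln) == 0L) stop("missing CIF tag ", tag)
    as.numeric(sub(paste0("^", tag, "\\s+"), "", ln[1L]))
  }
  cell <- c(getnum("_cell_length_a"), getnum("_cell_length_b"),
            getnum("_cell_length_c"), getnum("_cell_angle_alpha"),
            getnum("_cell_angle_beta"), getnum("_cell_angle_gamma"))
  i <- grep("^_atom_site_fract_z", lines)
  if (length(i) == 0L) stop("no atom site loop")
  rows <- lines[(i[1L] + 1L):length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  parts <- strsplit(trimws(rows), "\\s+")
  frac <- t(vapply(parts, function(p) as.numeric(p[3:5]), numeric(3)))
  labels <- vapply(parts, `[`, "", 1L)
  list(cell = cell, frac = frac, labels = labels)
}

## ---------------------------------------------------------------------------
## JSONL record streams

.record_to_list <- function(r) {
  list(schema = .SCHEMA,
       U_unb = r$U_unb, penalty = r$penalty, U_biased = r$U_biased,
       converged = r$converged, provenance = r$provenance, seed = r$seed,
       state = list(com = r$state$com, euler = r$state$euler,
                    cell = r$state$cell))
}

.record_from_list <- function(x, line) {
  if (is.null(x$schema) || !identical(x$schema, .SCHEMA))
    stop("schema mismatch at line ", line, ": expected ", .SCHEMA)
  st <- packing_state(x$state$com, x$state$euler, x$state$cell)
  polymorph_record(st, x$U_unb, x$penalty,
                   converged = isTRUE(x$converged),
                   provenance = as.list(x$provenance),
                   seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Write polymorph records as JSONL
#'
#' One JSON object per line; full double precision; append mode allows
#' merging streams from several runs (distinguished by their provenance run
#' ids).
#'
#' @param records List of `polymorph_record`s (or an object carrying
#'   `records`).
#' @param path Output file.
#' @param append Append instead of truncate.
#' @return `path`, invisibly.
#' @export
write_records_jsonl <- function(records, path, append = FALSE) {
  if (!is.null(records$records)) records <- records$records
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(.record_to_list(r), auto_unbox = TRUE,
                                digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' Read polymorph records from JSONL
#'
#' @param path File written by [write_records_jsonl()].
#' @return List of `polymorph_record`s.
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE),
                  error = function(e)
                    stop("malformed JSONL at line ", i, ": ",
                         conditionMessage(e)))
    .record_from_list(x, i)
  })
}

#' Write an EVCCP trajectory as JSONL
#'
#' First line is a header (schema, config); each further line is one step
#' with its EV state, conditional energy, acceptance flag and mini-batch
#' records.
#'
#' @param traj An `evccp_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(schema = .SCHEMA, kind = "trajectory",
              cfg = traj$cfg[setdiff(names(traj$cfg), "coupling")],
              k_com = traj$cfg$coupling$k_com,
              k_euler = traj$cfg$coupling$k_euler,
              surrogate = traj$surrogate)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  for (s in traj$steps) {
    x <- list(iter = s$iter,
              S = list(com = s$S$com, euler = s$S$euler, box = s$S$box),
              U_cond = s$U_cond, accepted = s$accepted,
              n_prefiltered = s$n_prefiltered,
              records = lapply(s$records, .record_to_list))
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read an EVCCP trajectory from JSONL
#'
#' @param path File written by [write_trajectory_jsonl()].
#' @return List with `header` and `steps` (each step carrying `iter`, `S`
#'   as an `ev_state`, `U_cond`, `accepted`, `records`).
#' @export
read_trajectory_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty trajectory file")
  hdr <- jsonlite::fromJSON(lines[1L], simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (is.null(hdr$schema) || !identical(hdr$schema, .SCHEMA))
    stop("schema mismatch at line 1: expected ", .SCHEMA)
  steps <- lapply(seq_along(lines)[-1L], function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE),
                  error = function(e)
                    stop("malformed JSONL at line ", i, ": ",
                         conditionMessage(e)))
    recs <- x$records
    recs <- if (length(recs) == 0L) list()
            else lapply(seq_along(recs), function(j)
              .record_from_list(recs[[j]], i))
    list(iter = x$iter,
         S = ev_state(x$S$com, x$S$euler, box = x$S$box),
         U_cond = x$U_cond, accepted = x$accepted,
         n_prefiltered = x$n_prefiltered, records = recs)
  })
  list(header = hdr, steps = steps)
}

#' Read a molecule definition from JSON or YAML
#'
#' Expects fields `label`, `sites` (n x 3), `epsilon`, `sigma`, `charge`,
#' `molar_mass`.
#'
#' @param path File ending in .json, .yml or .yaml.
#' @return A [rigid_molecule()].
#' @export
read_molecule <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML input")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  sites <- x$sites
  if (is.list(sites)) sites <- do.call(rbind, sites)
  rigid_molecule(x$label, sites, x$epsilon, x$sigma, x$charge, x$molar_mass)
}
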