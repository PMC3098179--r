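# Text formats of the screen: PDBQT ligands with torsion trees, key/value
# docking parameter files, ASCII grid maps and the grid index, docking logs
# and the job-list file. All readers accept either a file path or literal
# text lines; all writers emit deterministic text.

.as_lines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) return(as.character(text))
  if (is.null(file)) stop("supply either `file` or `text`")
  if (!file.exists(file)) stop("cannot read '", file, "': no such file")
  readLines(file, warn = FALSE)
}

#' Read a PDBQT ligand
#'
#' Parses ATOM/HETATM records and the ROOT/BRANCH torsion-tree block
#' structure into a `ligand` object: an ordered atom table (name,
#' coordinates in Angstrom, partial charge in elementary-charge units, atom
#' type), rigid groups, and one rotatable bond per `BRANCH` record with the
#' set of atom indices it moves.
#'
#' Dialect notes: the partial charge and atom type are taken positionally
#' from the last two whitespace-delimited fields of each atom record, and
#' the coordinates from the three fields preceding occupancy and temperature
#' factor; this tolerates the column drift of different preparation tools.
#' Atom indices are 1-based in order of appearance; `BRANCH i j` refers to
#' serial numbers in the file.
#'
#' @param file path to a `.pdbqt` file.
#' @param text alternatively, a character vector of lines.
#' @return an object of class `ligand` with elements `atoms` (data.frame
#'   `name`, `x`, `y`, `z`, `charge`, `type`), `root` (atom indices of the
#'   root rigid group), `groups` (list of atom-index vectors, root first),
#'   `edges` (list of rotatable bonds, each `list(i, j, moved)` in pre-order
#'   from the root), `n_torsions`, and `source_id`.
#' @export
read_pdbqt <- function(file = NULL, text = NULL) {
  lines <- .as_lines(file, text)
  source_id <- if (!is.null(file)) file else "text"

  atoms <- list()
  serial2idx <- integer(0)
  # tree state: stack of open groups; each frame holds the group's atoms and
  # its opening bond serials
  root_open <- FALSE
  root_closed <- FALSE
  stack <- list()
  groups <- list()      # filled on close, re-ordered later
  edges <- list()       # list(i, j, moved, order) with pre-order rank
  order_counter <- 0L
  root_atoms <- integer(0)
  # subtree accumulation: each stack frame collects all atoms beneath it
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "") next
    rec <- tok[1]
    if (rec %in% c("ATOM", "HETATM")) {
      n <- length(tok)
      if (n < 9) stop("line ", ln, ": atom record too short")
      charge <- suppressWarnings(as.numeric(tok[n - 1]))
      if (is.na(charge)) {
        stop("line ", ln, ": non-numeric partial charge '", tok[n - 1], "'")
      }
      xyz <- suppressWarnings(as.numeric(tok[(n - 6):(n - 4)]))
      if (anyNA(xyz) || !all(is.finite(xyz))) {
        stop("line ", ln, ": non-numeric coordinates")
      }
      serial <- suppressWarnings(as.integer(tok[2]))
      idx <- length(atoms) + 1L
      atoms[[idx]] <- list(name = tok[3], x = xyz[1], y = xyz[2], z = xyz[3],
                           charge = charge, type = tok[n])
      if (!is.na(serial)) serial2idx[as.character(serial)] <- idx
      if (length(stack) == 0) {
        if (root_closed || !root_open) {
          stop("line ", ln, ": atom record outside ROOT/BRANCH blocks")
        }
        root_atoms <- c(root_atoms, idx)
      } else {
        top <- length(stack)
        stack[[top]]$atoms <- c(stack[[top]]$atoms, idx)
        stack[[top]]$subtree <- c(stack[[top]]$subtree, idx)
      }
    } else if (rec == "ROOT") {
      root_open <- TRUE
    } else if (rec == "ENDROOT") {
      root_open <- FALSE
      root_closed <- TRUE
    } else if (rec == "BRANCH") {
      if (length(tok) < 3) stop("line ", ln, ": BRANCH needs two atom serials")
      stack[[length(stack) + 1L]] <- list(
        si = tok[2], sj = tok[3], atoms = integer(0), subtree = integer(0),
        line = ln)
      order_counter <- order_counter + 1L
      stack[[length(stack)]]$order <- order_counter
    } else if (rec == "ENDBRANCH") {
      if (length(stack) == 0) {
        stop("line ", ln, ": ENDBRANCH without matching BRANCH")
      }
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      edges[[length(edges) + 1L]] <- list(
        si = top$si, sj = top$sj, group = top$atoms, moved = top$subtree,
        order = top$order)
      if (length(stack) > 0) {
        k <- length(stack)
        stack[[k]]$subtree <- c(stack[[k]]$subtree, top$subtree)
      }
    }
    # TORSDOF and REMARK lines are ignored
  }
  if (length(stack) > 0) {
    stop("line ", stack[[length(stack)]]$line,
         ": BRANCH never closed (unbalanced nesting)")
  }
  if (length(atoms) == 0) stop("no atom records found")

  atoms_df <- data.frame(
    name = vapply(atoms, `[[`, "", "name"),
    x = vapply(atoms, `[[`, 0, "x"),
    y = vapply(atoms, `[[`, 0, "y"),
    z = vapply(atoms, `[[`, 0, "z"),
    charge = vapply(atoms, `[[`, 0, "charge"),
    type = vapply(atoms, `[[`, "", "type"),
    stringsAsFactors = FALSE)

  # resolve BRANCH serials to atom indices and order edges root-outward
  resolve <- function(s, what) {
    idx <- serial2idx[[s]]
    if (is.null(idx) || is.na(idx)) {
      stop("BRANCH refers to unknown atom serial ", s, " (", what, ")")
    }
    idx
  }
  edges <- edges[order(vapply(edges, `[[`, 0L, "order"))]
  edges <- lapply(edges, function(e) {
    list(i = resolve(e$si, "proximal"), j = resolve(e$sj, "distal"),
         moved = sort(e$moved), group = sort(e$group))
  })

  structure(list(
    atoms = atoms_df,
    root = root_atoms,
    groups = c(list(root_atoms), lapply(edges, `[[`, "group")),
    edges = edges,
    n_torsions = length(edges),
    source_id = source_id
  ), class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  cat("PDBQT ligand:", nrow(x$atoms), "atoms,", x$n_torsions, "torsions",
      sprintf("(%s)\n", x$source_id))
  invisible(x)
}

#' Write a PDBQT ligand
#'
#' Serializes a `ligand` back to PDBQT text, reconstructing the
#' ROOT/BRANCH block structure from the torsion tree. Round-trips with
#' [read_pdbqt()].
#'
#' @param ligand a `ligand` object.
#' @param file output path; omit to return the lines invisibly.
#' @return the character vector of lines, invisibly.
#' @export
write_pdbqt <- function(ligand, file = NULL) {
  at <- ligand$atoms
  atom_line <- function(i) {
    sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  0.00  0.00    %+7.4f %-2s",
            i, at$name[i], at$x[i], at$y[i], at$z[i], at$charge[i], at$type[i])
  }
  # children of each node (root = 0) in pre-order, reconstructed from the
  # nesting implied by moved-set containment
  n_edges <- length(ligand$edges)
  parent <- integer(n_edges)  # 0 = root
  if (n_edges > 0) {
    for (k in seq_len(n_edges)) {
      parent[k] <- 0L
      if (k > 1) {
        for (p in (k - 1):1) {
          if (all(ligand$edges[[k]]$moved %in% ligand$edges[[p]]$moved)) {
            parent[k] <- p
            break
          }
        }
      }
    }
  }
  out <- character(0)
  emit <- function(node) {
    kids <- if (n_edges > 0) which(parent == node) else integer(0)
    if (node == 0L) {
      out <<- c(out, "ROOT")
      for (i in ligand$root) out <<- c(out, atom_line(i))
      out <<- c(out, "ENDROOT")
    } else {
      e <- ligand$edges[[node]]
      out <<- c(out, sprintf("BRANCH %d %d", e$i, e$j))
      for (i in e$group) out <<- c(out, atom_line(i))
    }
    for (k in kids) emit(k)
    if (node != 0L) {
      e <- ligand$edges[[node]]
      out <<- c(out, sprintf("ENDBRANCH %d %d", e$i, e$j))
    }
  }
  emit(0L)
  out <- c(out, sprintf("TORSDOF %d", ligand$n_torsions))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

# ---------------------------------------------------------------------------

.param_defaults <- function() {
  list(
    ga_runs = 20L,
    ga_popsize = 150L,
    ga_num_evals = 250000L,
    ga_num_generations = 27000L,
    ls_frequency = 0.06,
    cluster_tolerance = 2.0,
    map_policy = "reuse",
    seed = "time"
  )
}

.count_keys <- c("ga_runs", "ga_popsize", "ga_num_evals", "ga_num_generations")

#' Docking parameters
#'
#' Constructor with the engine defaults: 20 LGA runs per docking, population
#' size 150, an energy-evaluation budget of 250000, a generation budget of
#' 27000, local-search frequency 0.06, 2.0 Angstrom clustering tolerance,
#' grid-map `reuse` policy, and a time-sampled base seed.
#'
#' @param ... named overrides of any default.
#' @return an object of class `docking_parameters`.
#' @export
docking_parameters <- function(...) {
  p <- .param_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  .validate_parameters(p)
}

.validate_parameters <- function(p) {
  for (k in .count_keys) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v != as.integer(v)) {
      stop("parameter '", k, "' must be a single integer")
    }
    if (v < 0) stop("parameter '", k, "' must be non-negative")
    p[[k]] <- as.integer(v)
  }
  if (p$ga_runs < 1) stop("ga_runs must be >= 1")
  if (p$ga_popsize < 1) stop("ga_popsize must be >= 1")
  if (!is.numeric(p$ls_frequency) || p$ls_frequency < 0 || p$ls_frequency > 1) {
    stop("ls_frequency must lie in [0, 1]")
  }
  if (!is.numeric(p$cluster_tolerance) || p$cluster_tolerance <= 0) {
    stop("cluster_tolerance must be > 0")
  }
  if (!p$map_policy %in% c("reuse", "reload")) {
    stop("map_policy must be 'reuse' or 'reload'")
  }
  if (!identical(p$seed, "time")) {
    sv <- suppressWarnings(as.numeric(p$seed))
    if (is.na(sv) || sv != floor(sv)) stop("seed must be an integer or 'time'")
    p$seed <- sv
  }
  structure(p, class = "docking_parameters")
}

#' Parse a docking parameter file
#'
#' One `key value` pair per line; `#` starts a comment; later occurrences of
#' a key override earlier ones; unrecognized keys are kept (and warned
#' about) but ignored by the engine. Recognized keys: `ga_runs`,
#' `ga_popsize`, `ga_num_evals`, `ga_num_generations`, `ls_frequency`,
#' `cluster_tolerance`, `map_policy`, `seed`.
#'
#' @inheritParams read_pdbqt
#' @param quiet suppress the unknown-key warning.
#' @return a `docking_parameters` object; unknown pairs are preserved in
#'   `attr(, "extra")`.
#' @export
parse_parameters <- function(file = NULL, text = NULL, quiet = FALSE) {
  lines <- .as_lines(file, text)
  p <- .param_defaults()
  extra <- list()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[ln]])
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "") next
    key <- tok[1]
    val <- if (length(tok) >= 2) tok[2] else ""
    if (key %in% .count_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num) || num != floor(num)) {
        stop("line ", ln, ": '", key, "' needs an integer, got '", val, "'")
      }
      if (num < 0) stop("line ", ln, ": '", key, "' must be non-negative")
      p[[key]] <- as.integer(num)
    } else if (key %in% c("ls_frequency", "cluster_tolerance")) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("line ", ln, ": '", key, "' needs a number")
      p[[key]] <- num
    } else if (key == "map_policy") {
      p[[key]] <- val
    } else if (key == "seed") {
      p[[key]] <- if (identical(val, "time")) "time" else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("line ", ln, ": 'seed' needs an integer or 'time'")
        num
      }
    } else {
      extra[[key]] <- val
      if (!quiet) warning("ignoring unknown parameter key '", key, "'",
                          call. = FALSE)
    }
  }
  out <- .validate_parameters(p)
  attr(out, "extra") <- extra
  out
}

#' Serialize docking parameters
#'
#' Writes one `key value` pair per line in a fixed key order, so that
#' `parse_parameters(text = write_parameters(p))` reproduces `p`.
#'
#' @param params a `docking_parameters` object.
#' @param file optional output path.
#' @return the lines, invisibly.
#' @export
write_parameters <- function(params, file = NULL) {
  keys <- names(.param_defaults())
  out <- vapply(keys, function(k) {
    v <- params[[k]]
    paste(k, format(v, scientific = FALSE))
  }, "")
  if (!is.null(file)) writeLines(out, file)
  invisible(unname(out))
}

#' @export
print.docking_parameters <- function(x, ...) {
  cat("docking parameters:\n")
  for (k in names(.param_defaults())) cat(" ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Read an ASCII grid map
#'
#' Header lines `SPACING`, `NELEMENTS` (three equal even interval counts),
#' `CENTER` and `TYPE` may appear in any order before the data; the data is
#' exactly `(npts + 1)^3` values, one per line, in x-fastest / z-slowest
#' lattice order. Values are stored so that `values[ix, iy, iz]` (1-based)
#' is the lattice point at zero-based index `(ix-1, iy-1, iz-1)`.
#'
#' @inheritParams read_pdbqt
#' @return a `grid_map` object: `header` (`spacing`, `npts`, `center`,
#'   `atom_type`), `values` (a 3-D array), `origin` (lower box corner,
#'   `center - npts * spacing / 2`).
#' @seealso [write_map()], [grid_map()]
#' @export
read_map <- function(file = NULL, text = NULL) {
  lines <- .as_lines(file, text)
  spacing <- npts <- center <- atom_type <- NULL
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "") { i <- i + 1L; next }
    key <- toupper(tok[1])
    if (key == "SPACING") {
      spacing <- as.numeric(tok[2])
    } else if (key == "NELEMENTS") {
      npts3 <- as.integer(tok[2:4])
      if (anyNA(npts3) || length(unique(npts3)) != 1) {
        stop("NELEMENTS must be three equal counts")
      }
      if (npts3[1] %% 2 != 0 || npts3[1] < 2) {
        stop("NELEMENTS must be even and >= 2, got ", npts3[1])
      }
      npts <- npts3[1]
    } else if (key == "CENTER") {
      center <- as.numeric(tok[2:4])
    } else if (key == "TYPE") {
      atom_type <- tok[2]
    } else {
      break  # first data line
    }
    i <- i + 1L
  }
  if (is.null(spacing) || is.null(npts) || is.null(center) || is.null(atom_type)) {
    stop("map header incomplete: need SPACING, NELEMENTS, CENTER, TYPE")
  }
  n <- npts + 1L
  expected <- n^3
  data_lines <- lines[i:length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != expected) {
    stop("map truncated or overlong: expected ", expected, " values, found ",
         length(data_lines))
  }
  vals <- as.numeric(data_lines)
  if (anyNA(vals)) stop("non-numeric map value")
  grid_map(spacing = spacing, npts = npts, center = center,
           atom_type = atom_type, values = array(vals, dim = c(n, n, n)))
}

#' Write an ASCII grid map
#'
#' Fixed header order (SPACING, NELEMENTS, CENTER, TYPE) followed by one
#' value per line in x-fastest order. Values are printed with `%.17g`, so a
#' read/write cycle is the identity on the numeric content and a second
#' write is byte-identical to the first.
#'
#' @param map a `grid_map`.
#' @param file optional output path.
#' @return the lines, invisibly.
#' @export
write_map <- function(map, file = NULL) {
  h <- map$header
  out <- c(
    sprintf("SPACING %.17g", h$spacing),
    sprintf("NELEMENTS %d %d %d", h$npts, h$npts, h$npts),
    sprintf("CENTER %.17g %.17g %.17g", h$center[1], h$center[2], h$center[3]),
    paste("TYPE", h$atom_type),
    sprintf("%.17g", as.vector(map$values))
  )
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Read a grid index file
#'
#' One line per map: `atom_type filename` (filename relative to the index
#' file's directory). Reserved types `e` and `d` name the electrostatic and
#' desolvation maps.
#'
#' @param file path to the `.fld`-like index.
#' @return named character vector mapping atom type to absolute map path.
#' @export
read_fld <- function(file) {
  lines <- .as_lines(file = file)
  dir <- dirname(file)
  out <- character(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "" || startsWith(tok[1], "#")) next
    if (length(tok) < 2) stop("line ", ln, ": need 'atom_type filename'")
    out[tok[1]] <- file.path(dir, tok[2])
  }
  out
}

#' Write a grid index file
#'
#' @param types named character vector: atom type -> map filename (relative
#'   paths are kept as written).
#' @param file output path.
#' @export
write_fld <- function(types, file) {
  writeLines(paste(names(types), unname(types)), file)
  invisible(file)
}

# ---------------------------------------------------------------------------

#' Write a docking log
#'
#' Emits the package's docking-log dialect: a header, then each run's
#' buffered log contiguously (runs in run-index order, each bracketed by
#' `Run N` / `End Run N` markers), then the clustering and ranking sections.
#' Because every run's lines are buffered during the search and written en
#' bloc here, the text is identical however many threads executed the runs.
#'
#' @param result a `docking_result`.
#' @param file optional output path.
#' @return the lines, invisibly.
#' @export
write_dlg <- function(result, file = NULL) {
  runs <- result$runs
  for (k in seq_along(runs)) {
    if (is.null(runs[[k]]$log_buffer)) {
      stop("run ", k, " has no log buffer; result is incomplete")
    }
  }
  out <- c(
    "DOCKING LOG",
    paste("job:", result$job_id),
    paste("runs:", length(runs)))
  for (k in seq_along(runs)) {
    r <- runs[[k]]
    out <- c(out,
             sprintf("Run %d", k),
             sprintf("seed: %.0f", r$seed),
             r$log_buffer,
             sprintf("best_energy: %.6f", r$best_energy),
             sprintf("End Run %d", k))
  }
  out <- c(out, sprintf("CLUSTERING tolerance %.3f A", result$cluster_tolerance))
  for (c_i in seq_along(result$clusters)) {
    members <- result$clusters[[c_i]]
    best <- runs[[members[1]]]$best_energy
    out <- c(out, sprintf("cluster %d: size %d best_energy %.6f runs %s",
                          c_i, length(members), best,
                          paste(members, collapse = ",")))
  }
  out <- c(out, "RANKING")
  for (c_i in seq_along(result$clusters)) {
    lead <- result$clusters[[c_i]][1]
    out <- c(out, sprintf("rank %d cluster %d run %d energy %.6f",
                          c_i, c_i, lead, runs[[lead]]$best_energy))
  }
  out <- c(out, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
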