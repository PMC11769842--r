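# Atomic configurations, extended-XYZ exchange, neighbour lists and element
# attributes.

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

symbol_to_z <- function(sym) {
  z <- match(sym, ELEMENT_SYMBOLS)
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(unique(sym[is.na(z)]), collapse = ", "))
  z
}

#' Atomic configuration
#'
#' The unit of all package I/O: positions and atomic numbers, with optional
#' periodic cell, reference energy (eV) and forces (eV/Angstrom).
#'
#' @param positions `n_atoms x 3` matrix, Angstrom.
#' @param atomic_numbers integer vector, >= 1.
#' @param cell optional `3 x 3` matrix of lattice row vectors, Angstrom.
#' @param pbc logical length-3; defaults to all TRUE when a cell is given.
#' @param energy optional scalar energy label, eV.
#' @param forces optional `n_atoms x 3` force labels, eV/Angstrom.
#' @return object of class `atomic_configuration`.
#' @export
atomic_configuration <- function(positions, atomic_numbers, cell = NULL,
                                 pbc = NULL, energy = NULL, forces = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  stopifnot(ncol(positions) == 3L, all(is.finite(positions)))
  atomic_numbers <- as.integer(atomic_numbers)
  stopifnot(length(atomic_numbers) == nrow(positions), all(atomic_numbers >= 1L))
  if (!is.null(cell)) {
    cell <- as.matrix(cell)
    stopifnot(all(dim(cell) == c(3L, 3L)), all(is.finite(cell)))
    if (is.null(pbc)) pbc <- c(TRUE, TRUE, TRUE)
  } else if (is.null(pbc)) {
    pbc <- c(FALSE, FALSE, FALSE)
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    stopifnot(all(dim(forces) == dim(positions)))
  }
  structure(list(positions = positions, atomic_numbers = atomic_numbers,
                 cell = cell, pbc = as.logical(pbc),
                 energy = if (is.null(energy)) NULL else as.numeric(energy),
                 forces = forces),
            class = "atomic_configuration")
}

#' @export
print.atomic_configuration <- function(x, ...) {
  cat("atomic_configuration:", nrow(x$positions), "atoms (",
      paste(ELEMENT_SYMBOLS[sort(unique(x$atomic_numbers))], collapse = " "),
      ")", if (!is.null(x$cell)) "periodic" else "non-periodic",
      if (!is.null(x$energy)) sprintf("E = %.6f eV", x$energy) else "", "\n")
  invisible(x)
}

n_atoms <- function(config) nrow(config$positions)

# ---- extended XYZ -----------------------------------------------------------

# Tokenize an extxyz comment line into a named list; values may be quoted.
parse_extxyz_comment <- function(line) {
  out <- list()
  pat <- '([A-Za-z0-9_:-]+)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    tok <- substr(line, starts[i], starts[i] + lens[i] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  names(out) <- tolower(names(out))
  out
}

#' Read configurations from an extended XYZ file
#'
#' Parses the ASE dialect: `Lattice="..."`, `Properties=species:S:1:pos:R:3
#' [:forces:R:3]`, `energy=...` and `pbc="T T F"` in the comment line.  Frames
#' without force (energy) columns get a `NULL` forces (energy) field.
#'
#' @param path file path.
#' @return list of [atomic_configuration()] objects, one per frame.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("read_extxyz: no such file: ", path)
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L || i + 1L + nat > length(lines) + 0L) {
      stop("read_extxyz: malformed frame ", frame, " at line ", i)
    }
    info <- parse_extxyz_comment(lines[i + 1L])
    props <- info[["properties"]] %||% "species:S:1:pos:R:3"
    fields <- strsplit(props, ":")[[1]]
    if (length(fields) %% 3 != 0) {
      stop("read_extxyz: malformed Properties in frame ", frame)
    }
    pnames <- fields[seq(1, length(fields), by = 3)]
    pcount <- as.integer(fields[seq(3, length(fields), by = 3)])
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    ncols <- sum(pcount)
    if (any(vapply(toks, length, 1L) != ncols)) {
      stop("read_extxyz: wrong column count in frame ", frame)
    }
    tab <- do.call(rbind, toks)
    col <- 1L
    species <- NULL; pos <- NULL; forces <- NULL
    for (k in seq_along(pnames)) {
      cols <- col:(col + pcount[k] - 1L)
      if (pnames[k] == "species") {
        species <- tab[, cols[1]]
      } else if (pnames[k] == "pos") {
        pos <- matrix(as.numeric(tab[, cols]), nat, 3)
      } else if (pnames[k] %in% c("forces", "force")) {
        forces <- matrix(as.numeric(tab[, cols]), nat, 3)
      }
      col <- col + pcount[k]
    }
    if (is.null(species) || is.null(pos) || anyNA(pos)) {
      stop("read_extxyz: frame ", frame, " lacks species/pos data")
    }
    cell <- NULL
    if (!is.null(info[["lattice"]])) {
      v <- as.numeric(strsplit(trimws(info[["lattice"]]), "\\s+")[[1]])
      if (length(v) != 9 || anyNA(v)) {
        stop("read_extxyz: malformed Lattice in frame ", frame)
      }
      cell <- matrix(v, 3, 3, byrow = TRUE)
    }
    pbc <- NULL
    if (!is.null(info[["pbc"]])) {
      pbc <- toupper(strsplit(trimws(info[["pbc"]]), "\\s+")[[1]]) %in% c("T", "TRUE")
    }
    energy <- if (!is.null(info[["energy"]])) as.numeric(info[["energy"]]) else NULL
    configs[[frame]] <- atomic_configuration(
      positions = pos, atomic_numbers = symbol_to_z(species),
      cell = cell, pbc = pbc, energy = energy, forces = forces
    )
    i <- i + 2L + nat
  }
  configs
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write configurations to an extended XYZ file
#'
#' Standard extxyz with `Lattice`/`Properties` headers and 17 significant
#' digits, so a write/read round trip reproduces coordinates and labels to
#' float64 precision.
#'
#' @param configs an [atomic_configuration()] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(configs, path) {
  if (inherits(configs, "atomic_configuration")) configs <- list(configs)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("write_extxyz: cannot open ", path, " (", conditionMessage(e), ")")
  })
  on.exit(close(con))
  for (cfg in configs) {
    nat <- n_atoms(cfg)
    props <- "species:S:1:pos:R:3"
    if (!is.null(cfg$forces)) props <- paste0(props, ":forces:R:3")
    header <- sprintf('Properties=%s', props)
    if (!is.null(cfg$cell)) {
      header <- paste0(
        'Lattice="', paste(fmt17(as.vector(t(cfg$cell))), collapse = " "),
        '" ', header,
        ' pbc="', paste(ifelse(cfg$pbc, "T", "F"), collapse = " "), '"'
      )
    }
    if (!is.null(cfg$energy)) {
      header <- paste0(header, " energy=", fmt17(cfg$energy))
    }
    writeLines(as.character(nat), con)
    writeLines(header, con)
    sym <- ELEMENT_SYMBOLS[cfg$atomic_numbers]
    for (a in seq_len(nat)) {
      row <- c(sym[a], fmt17(cfg$positions[a, ]))
      if (!is.null(cfg$forces)) row <- c(row, fmt17(cfg$forces[a, ]))
      writeLines(paste(row, collapse = " "), con)
    }
  }
  invisible(path)
}

# ---- neighbour lists --------------------------------------------------------

#' Directed neighbour list within a cutoff
#'
#' All directed pairs with distance strictly below `r_cut`; periodic images are
#' included by explicit cell replication sufficient for the cutoff.  Edges are
#' sorted canonically by (receiver, sender, shift) so downstream summations are
#' bit-reproducible under any input permutation of the edges.
#'
#' @param config an [atomic_configuration()].
#' @param r_cut cutoff radius, Angstrom, > 0.
#' @return object of class `neighbour_list`: `receivers`, `senders` (1-based),
#'   `shifts` (`n_edges x 3` integer lattice shifts), `displacements`
#'   (`n_edges x 3`, `r_j - r_i` plus shift), `distances`, `r_cut`.
#' @export
build_neighbour_list <- function(config, r_cut) {
  stopifnot(r_cut > 0)
  pos <- config$positions
  nat <- nrow(pos)
  periodic <- !is.null(config$cell) && any(config$pbc)
  if (!periodic) {
    shifts <- matrix(0L, 1, 3)
    offsets <- matrix(0, 1, 3)
  } else {
    cell <- config$cell
    # Replication bound per axis from the cell's perpendicular heights.
    heights <- vapply(1:3, function(k) {
      others <- setdiff(1:3, k)
      nvec <- pracma_cross(cell[others[1], ], cell[others[2], ])
      abs(sum(cell[k, ] * nvec)) / sqrt(sum(nvec^2))
    }, 1)
    if (any(!is.finite(heights)) || any(heights <= 0)) {
      stop("build_neighbour_list: degenerate cell")
    }
    nrep <- ifelse(config$pbc, ceiling(r_cut / heights), 0L)
    if (any(nrep > 12)) {
      stop("build_neighbour_list: cell too skewed/small for this cutoff")
    }
    grid <- expand.grid(a = -nrep[1]:nrep[1], b = -nrep[2]:nrep[2],
                        c = -nrep[3]:nrep[3])
    shifts <- as.matrix(grid)
    storage.mode(shifts) <- "integer"
    offsets <- shifts %*% cell
  }
  rec <- sen <- integer(0)
  sh <- matrix(integer(0), 0, 3)
  disp <- matrix(numeric(0), 0, 3)
  for (s in seq_len(nrow(shifts))) {
    off <- offsets[s, ]
    zero_shift <- all(shifts[s, ] == 0L)
    # displacement r_j + shift - r_i for all ordered (i, j)
    dx <- outer(pos[, 1], pos[, 1], function(a, b) b - a) + off[1]
    dy <- outer(pos[, 2], pos[, 2], function(a, b) b - a) + off[2]
    dz <- outer(pos[, 3], pos[, 3], function(a, b) b - a) + off[3]
    d2 <- dx^2 + dy^2 + dz^2
    keep <- d2 < r_cut^2
    if (zero_shift) diag(keep) <- FALSE
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx)) {
      rec <- c(rec, idx[, 1])
      sen <- c(sen, idx[, 2])
      sh <- rbind(sh, matrix(shifts[s, ], nrow(idx), 3, byrow = TRUE))
      disp <- rbind(disp, cbind(dx[idx], dy[idx], dz[idx]))
    }
  }
  ord <- order(rec, sen, sh[, 1], sh[, 2], sh[, 3])
  structure(list(receivers = rec[ord], senders = sen[ord],
                 shifts = sh[ord, , drop = FALSE],
                 displacements = disp[ord, , drop = FALSE],
                 distances = row_norms(disp[ord, , drop = FALSE]),
                 r_cut = r_cut, n_atoms = nat),
            class = "neighbour_list")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Recompute displacement vectors for a (possibly complex-perturbed) position
# matrix on a fixed edge list; the graph itself is never differentiated.
edge_displacements <- function(nl, positions, cell = NULL) {
  disp <- positions[nl$senders, , drop = FALSE] -
    positions[nl$receivers, , drop = FALSE]
  if (!is.null(cell) && nrow(nl$shifts)) {
    disp <- disp + nl$shifts %*% cell
  }
  disp
}

#' One-hot element attributes
#'
#' @param atomic_numbers integer atomic numbers.
#' @param element_table ascending vector of atomic numbers known to the model.
#' @return object of class `node_attributes`: `one_hot`
#'   (`n_atoms x n_elements`) and `element_table`.
#' @export
one_hot_attributes <- function(atomic_numbers, element_table) {
  idx <- match(atomic_numbers, element_table)
  if (anyNA(idx)) {
    stop("one_hot_attributes: unknown atomic number(s): ",
         paste(unique(atomic_numbers[is.na(idx)]), collapse = ", "))
  }
  oh <- matrix(0, length(atomic_numbers), length(element_table))
  oh[cbind(seq_along(idx), idx)] <- 1
  structure(list(one_hot = oh, element_table = element_table,
                 indices = idx),
            class = "node_attributes")
}
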