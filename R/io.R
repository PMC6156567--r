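#' Read a PDB structure with the package's altloc policy
#'
#' Parses ATOM/HETATM records (via bio3d) into a flat atom table. Alternate
#' locations are resolved to the highest-occupancy conformer; exact ties
#' keep altloc `'A'`. Residue numbering is preserved as deposited.
#'
#' @param path path to a PDB file
#' @return data.frame with columns `eleno`, `elety` (atom name), `resid`,
#'   `resno`, `chain`, `x`, `y`, `z`, `occupancy`, `altloc`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## validate coordinate fields before handing off to the parser
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(
      c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(coords))
      stop("malformed ATOM/HETATM record at line ", i)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  df <- data.frame(eleno = a$eleno, elety = a$elety, resid = a$resid,
                   resno = a$resno, chain = a$chain,
                   x = a$x, y = a$y, z = a$z,
                   occupancy = a$o,
                   altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
                   stringsAsFactors = FALSE)
  ## altloc policy: per (chain, resno, atom name) keep highest occupancy,
  ## ties -> 'A' (blank altloc sorts before 'A' and is kept as-is)
  key <- paste(df$chain, df$resno, df$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(ix) {
    if (length(ix) == 1) return(ix)
    occ <- df$occupancy[ix]
    best <- ix[occ == max(occ, na.rm = TRUE)]
    if (length(best) > 1) best <- best[order(df$altloc[best])][1]
    best
  }), use.names = FALSE)
  out <- df[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Write a multi-frame XYZ trajectory
#'
#' Plain XYZ: atom count, comment line, then `name x y z` per atom, with
#' coordinates at fixed precision.
#'
#' @param frames a single n x 3 matrix or a list of them
#' @param path output file
#' @param atom atom name labels (recycled across frames)
#' @param comment per-frame comment line(s)
#' @param digits coordinate decimals
#' @return `path`, invisibly
#' @export
write_xyz <- function(frames, path, atom = NULL, comment = "", digits = 6) {
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  comment <- rep_len(comment, length(frames))
  for (i in seq_along(frames)) {
    fr <- as.matrix(frames[[i]])
    nm <- if (is.null(atom)) rep("X", nrow(fr)) else rep_len(atom, nrow(fr))
    writeLines(as.character(nrow(fr)), con)
    writeLines(comment[i], con)
    writeLines(sprintf(paste0("%-4s %.", digits, "f %.", digits, "f %.",
                              digits, "f"),
                       nm, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file
#' @return list with `frames` (list of n x 3 matrices), `atom` (names from
#'   the first frame), `comments`; an empty file gives zero frames
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); comments <- character(0); atom <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1 + n > length(lines))
      stop("malformed XYZ: truncated frame at line ", i)
    comments <- c(comments, lines[i + 1])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4)
    if (length(bad)) stop("malformed XYZ atom line ", i + 1 + bad[1])
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(atom)) atom <- vapply(parts, `[[`, "", 1)
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  list(frames = frames, atom = atom, comments = comments)
}

#' Write an EVB system as YAML topology + XYZ coordinates
#'
#' The YAML carries atoms (names, masses, LJ), both valence-bond states
#' (charges, Morse/bond/angle terms, exclusions), coupling, droplet and
#' restraints; coordinates go to a sibling `.xyz` file. Supplementary
#' parameter tables transcribed by a user fit this format directly.
#'
#' @param system an [evb_system()]
#' @param path output YAML path (`.xyz` is derived from it)
#' @return `path`, invisibly
#' @export
write_evb_system <- function(system, path) {
  xyz_path <- sub("\\.ya?ml$", ".xyz", path)
  if (xyz_path == path) xyz_path <- paste0(path, ".xyz")
  st <- lapply(system$states, function(s)
    list(charges = as.numeric(s$charges),
         morse = .mat2list(s$morse), bonds = .mat2list(s$bonds),
         angles = .mat2list(s$angles), exclusions = .mat2list(s$exclusions)))
  obj <- list(
    atoms = list(name = as.character(system$atom),
                 mass = as.numeric(system$mass),
                 lj_sigma = as.numeric(system$lj_sigma),
                 lj_eps = as.numeric(system$lj_eps)),
    states = st,
    coupling = system$coupling,
    droplet_radius = system$droplet_radius, wall_k = system$wall_k,
    cutoff = system$cutoff, reacting = as.integer(system$reacting),
    posres = .mat2list(system$posres), distres = .mat2list(system$distres),
    constraints = .mat2list(system$constraints),
    solute = as.integer(system$solute),
    coordinates = basename(xyz_path))
  yaml::write_yaml(obj, path, precision = 12)
  write_xyz(system$xyz, xyz_path, atom = system$atom)
  invisible(path)
}

#' Read an EVB system written by [write_evb_system()]
#'
#' @param path YAML topology path
#' @return an [evb_system()]
#' @export
read_evb_system <- function(path) {
  obj <- yaml::read_yaml(path)
  xyz <- read_xyz(file.path(dirname(path), obj$coordinates))$frames[[1]]
  st <- lapply(obj$states, function(s)
    list(charges = as.numeric(s$charges), morse = .list2mat(s$morse, 5),
         bonds = .list2mat(s$bonds, 4), angles = .list2mat(s$angles, 5),
         exclusions = .list2mat(s$exclusions, 2)))
  evb_system(
    xyz = xyz, mass = obj$atoms$mass, atom = obj$atoms$name,
    lj_sigma = obj$atoms$lj_sigma, lj_eps = obj$atoms$lj_eps,
    state1 = st[[1]], state2 = st[[2]], coupling = obj$coupling,
    droplet_radius = obj$droplet_radius %||% Inf, wall_k = obj$wall_k %||% 0,
    cutoff = obj$cutoff, reacting = obj$reacting %||% integer(),
    posres = .list2mat(obj$posres, 5), distres = .list2mat(obj$distres, 4),
    constraints = .list2mat(obj$constraints, 3),
    solute = obj$solute)
}

.mat2list <- function(m) if (is.null(m) || nrow(m) == 0) list() else
  lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
.list2mat <- function(l, ncols) {
  if (is.null(l) || length(l) == 0) return(matrix(numeric(), 0, ncols))
  do.call(rbind, lapply(l, as.numeric))
}

#' Read/write rate tables as CSV
#'
#' Column layout `variant,isotope,conc_mM,temp_K,rate_per_s,replicate`,
#' decimal point ".", UTF-8.
#'
#' @param path CSV path
#' @return data.frame
#' @export
read_rate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant", "isotope", "conc_mM", "temp_K", "rate_per_s", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("rate CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$temp_K <= 0)) stop("rate CSV: non-positive temperature")
  df
}

#' @rdname read_rate_csv
#' @param table rate data.frame
#' @export
write_rate_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an analysis result to JSON
#'
#' @param x list of results (numbers, vectors, data frames)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run manifest for reproducibility records
#'
#' Captures package version, a config snapshot, the seed(s), md5 checksums
#' of input files and a timestamp; pipeline outputs can reference it.
#'
#' @param seed seed(s) used
#' @param config arbitrary config list to snapshot
#' @param inputs character vector of input file paths to checksum
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(seed, config = list(), inputs = character(0)) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(
    tool = "kemptools",
    version = as.character(utils::packageVersion("kemptools")),
    seed = seed, config = config, input_md5 = sums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}
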