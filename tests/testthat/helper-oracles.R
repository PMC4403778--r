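# Independent oracles used by the unit and acceptance tests. These stay
# independent of the implementation paths they check: plain double loops,
# textbook dynamic programming, derivative-free optimization, and an
# external cheminformatics toolkit.

# brute-force all-pairs site oracle: residue keys with any atom within
# radius of any ligand atom
oracle_site_residues <- function(s, lig_atoms, radius) {
  prot <- s$atoms[s$atoms$record == "polymer", , drop = FALSE]
  prot <- prot[prot$resname %in% c(names(getFromNamespace("AA3TO1", "mtlminer")), "MSE"), ,
               drop = FALSE]
  keys <- character(0)
  for (i in seq_len(nrow(prot))) {
    d <- sqrt((prot$x[i] - lig_atoms$x)^2 +
                (prot$y[i] - lig_atoms$y)^2 +
                (prot$z[i] - lig_atoms$z)^2)
    if (any(d <= radius)) {
      keys <- c(keys, paste(prot$chain[i], prot$resseq[i], prot$icode[i],
                            sep = "\r"))
    }
  }
  sort(unique(keys))
}

site_keys <- function(site) {
  if (site$residue_count == 0L) return(character(0))
  sort(paste(site$residues$chain, site$residues$resseq, site$residues$icode,
             sep = "\r"))
}

# textbook Gotoh affine-gap global alignment with the Biostrings cost
# convention: a gap of length L costs gapOpening + L * gapExtension.
# Returns the optimal score and the identity count of one optimal traceback.
oracle_gotoh <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  sm <- get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback for identical aligned positions
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n; j <- m; ident <- 0L
  while (i > 0 || j > 0) {
    if (state == 1L && i > 0 && j > 0) {
      if (av[i] == bv[j]) ident <- ident + 1L
      s <- sm[av[i], bv[j]]
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L && i > 0) {
      from_m <- M[i, j + 1] - gap_open - gap_ext
      from_x <- Ix[i, j + 1] - gap_ext
      state <- if (from_m >= from_x) 1L else 2L
      i <- i - 1L
    } else {
      from_m <- M[i + 1, j] - gap_open - gap_ext
      from_y <- Iy[i + 1, j] - gap_ext
      state <- if (from_m >= from_y) 1L else 3L
      j <- j - 1L
    }
  }
  list(score = score, nmatch = ident)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# derivative-free superposition oracle: optimal translation by centering,
# rotation minimized by multi-start Nelder-Mead over Euler angles
oracle_superpose_rmsd <- function(A, B, n_starts = 12) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rot <- function(th) {
    cx <- cos(th[1]); sx <- sin(th[1])
    cy <- cos(th[2]); sy <- sin(th[2])
    cz <- cos(th[3]); sz <- sin(th[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(th) {
    R <- rot(th)
    sqrt(mean(rowSums((A - B %*% t(R))^2)))
  }
  best <- Inf
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * (n_starts - 1), -pi, pi),
                         ncol = 3))
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    if (o$value < best) best <- o$value
  }
  best
}

# atomic weights typed independently from IUPAC 2021 for the formula oracle
ORACLE_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, CL = 35.45)
oracle_formula_weight <- function(elements) {
  sum(ORACLE_WEIGHTS[toupper(elements)])
}

# random rigid motion helper
random_rigid <- function() {
  M <- matrix(stats::rnorm(9), 3)
  q <- qr(M)
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::runif(3, -10, 10))
}

apply_rigid <- function(X, rg) {
  X %*% t(rg$R) + matrix(rg$t, nrow(X), 3, byrow = TRUE)
}

# random structure with a random ligand for site-oracle harnesses: residues
# and ligand atoms thrown uniformly into a box (no geometric idealization)
random_site_case <- function(n_res, box = 40) {
  aa <- names(getFromNamespace("AA3TO1", "mtlminer"))
  n_at <- sample(1:4, n_res, replace = TRUE)
  resseq <- rep(seq_len(n_res), n_at)
  k_in_res <- sequence(n_at)
  centers <- matrix(stats::runif(3 * n_res, 0, box), n_res, 3)
  n_prot <- length(resseq)
  xyz <- centers[resseq, , drop = FALSE] +
    matrix(stats::rnorm(3 * n_prot, sd = 1.2), n_prot, 3)
  res_name <- sample(aa, n_res, replace = TRUE)
  res_chain <- sample(c("A", "B"), n_res, replace = TRUE)
  prot <- data.frame(
    record = "polymer", serial = seq_len(n_prot),
    name = c("CA", "N", "C", "O")[k_in_res], alt_loc = "",
    resname = res_name[resseq], chain = res_chain[resseq],
    resseq = resseq, icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = c("C", "N", "C", "O")[k_in_res],
    stringsAsFactors = FALSE)
  n_lig <- sample(5:12, 1)
  lig_center <- stats::runif(3, 0, box)
  lxyz <- matrix(lig_center, n_lig, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n_lig, sd = 1.5), n_lig, 3)
  lig_df <- data.frame(
    record = "hetero", serial = n_prot + seq_len(n_lig),
    name = paste0("C", seq_len(n_lig)), alt_loc = "", resname = "LIG",
    chain = "X", resseq = 1L, icode = "", x = lxyz[, 1], y = lxyz[, 2],
    z = lxyz[, 3], occupancy = 1, element = "C", stringsAsFactors = FALSE)
  atoms <- rbind(prot, lig_df)
  s <- structure(list(structure_id = "RND1", experiment_method = "X-RAY",
                      resolution = 2.0, atoms = atoms, model_count = 1L),
                 class = "mtld_structure")
  lig <- structure(list(component_id = "LIG", chain_id = "X",
                        residue_seq = 1L, insertion_code = "",
                        atoms = atoms[atoms$record == "hetero", , drop = FALSE],
                        heavy_atom_count = n_lig,
                        source_structure_id = "RND1"),
                   class = "ligand_instance")
  list(s = s, lig = lig)
}

# ligand_instance wrapper around a raw atom table
as_instance <- function(atoms, component_id = "LIG", structure_id = "S000",
                        chain = "X", resseq = 1L) {
  atoms$record <- "hetero"
  structure(list(component_id = component_id, chain_id = chain,
                 residue_seq = as.integer(resseq), insertion_code = "",
                 atoms = atoms,
                 heavy_atom_count = sum(!(toupper(atoms$element) %in%
                                            c("H", "D"))),
                 source_structure_id = structure_id),
            class = "ligand_instance")
}

# V2000 MOL block (single bonds) from a molecular graph; coordinates are
# irrelevant to the descriptor oracle and written as zeros
mol_block <- function(g, title = "fixture") {
  n <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  lines <- c(title, "  mtltest", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    el <- g$atoms$element[i]
    el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, el))
  }
  if (nb > 0) {
    for (k in seq_len(nb)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", g$bonds[k, 1],
                                g$bonds[k, 2], 1L))
    }
  }
  c(lines, "M  END")
}

# batch RDKit descriptor oracle over an SDF of the graphs (same image as
# the grading container; no network)
rdkit_descriptors <- function(graphs) {
  sdf <- tempfile(fileext = ".sdf")
  out <- tempfile(fileext = ".tsv")
  writeLines(unlist(lapply(graphs, function(g) c(mol_block(g), "$$$$"))),
             sdf)
  py <- '
import sys
from rdkit import Chem
from rdkit.Chem import Descriptors, Lipinski
supp = Chem.SDMolSupplier(sys.argv[1], removeHs=False)
with open(sys.argv[2], "w") as fh:
    for mol in supp:
        if mol is None:
            fh.write("NA\\tNA\\tNA\\n")
            continue
        fh.write("%.4f\\t%d\\t%d\\n" % (Descriptors.HeavyAtomMolWt(mol),
                 Lipinski.NHOHCount(mol), Lipinski.NOCount(mol)))
'
  script <- tempfile(fileext = ".py")
  writeLines(py, script)
  status <- system2("python", c(script, sdf, out), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0L) stop("rdkit oracle failed")
  utils::read.table(out, sep = "\t",
                    col.names = c("heavy_mw", "nhoh", "no"))
}

# batch RDKit SMILES parser (sanitize off: bracket-atom connectivity SMILES)
rdkit_parse_counts <- function(smiles_vec) {
  infile <- tempfile(); out <- tempfile()
  writeLines(smiles_vec, infile)
  py <- '
import sys
from rdkit import Chem
with open(sys.argv[1]) as fh, open(sys.argv[2], "w") as oh:
    for line in fh:
        mol = Chem.MolFromSmiles(line.strip(), sanitize=False)
        if mol is None:
            oh.write("NA\\tNA\\tNA\\n")
            continue
        els = sorted(a.GetSymbol().upper() for a in mol.GetAtoms())
        oh.write("%d\\t%d\\t%s\\n" % (mol.GetNumAtoms(), mol.GetNumBonds(),
                 ",".join(els)))
'
  script <- tempfile(fileext = ".py")
  writeLines(py, script)
  status <- system2("python", c(script, infile, out), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0L) stop("rdkit parser failed")
  utils::read.table(out, sep = "\t",
                    col.names = c("n_atoms", "n_bonds", "elements"),
                    colClasses = c("integer", "integer", "character"))
}
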