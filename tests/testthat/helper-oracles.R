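# Brute-force oracles and fixture builders, independent of the package's
# distance kernels.

tree_of <- function(text) ape::read.tree(text = text)

# Nontrivial bipartitions as canonical strings, via ape's clade
# enumeration (independent of the package's C++ split encoding).
splits_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ref <- sort(labs)[1L]
  n <- length(labs)
  out <- character(0)
  for (s in pp) {
    if (length(s) >= 2L && length(s) <= n - 2L) {
      side <- sort(labs[s])
      if (ref %in% side) side <- sort(setdiff(labs, side))
      out <- c(out, paste(side, collapse = "|"))
    }
  }
  sort(unique(out))
}

rf_oracle <- function(t1, t2) {
  s1 <- splits_oracle(t1)
  s2 <- splits_oracle(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Exhaustive-subset MAST oracle: largest leaf subset whose restrictions
# are shape-equal, scanning subset sizes from n downward.
mast_oracle <- function(t1, t2) {
  lv <- t1$tip.label
  n <- length(lv)
  for (size in n:3) {
    for (s in utils::combn(n, size, simplify = FALSE)) {
      k1 <- ape::unroot(ape::keep.tip(t1, lv[s]))
      k2 <- ape::unroot(ape::keep.tip(t2, lv[s]))
      if (phangorn::RF.dist(k1, k2) == 0) return(size)
    }
  }
  2L
}

# A pair of distinct random topologies on shared labels.
random_pair <- function(n, seed) {
  t1 <- random_topology(n, seed = seed)
  t2 <- random_topology(n, seed = seed + 100000L)
  list(t1 = t1, t2 = t2)
}

quartet_ab <- function() tree_of("((A,B),(C,D));")
quartet_ac <- function() tree_of("((A,C),(B,D));")
quartet_ad <- function() tree_of("((A,D),(B,C));")

# Five-leaf caterpillar used across the worked TII examples.
full_five <- function() build_posterior(list(tree_of("((A,B),(C,(D,E)));")))

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Small MrBayes-style NEXUS trees block with a translate table.
nexus_trees_fixture <- function() {
  write_lines_tmp(c(
    "#NEXUS",
    "begin trees;",
    "   translate",
    "      1 Pelomedusa_subrufa,",
    "      2 Chelonia_mydas,",
    "      3 Alligator_mississippiensis,",
    "      4 Caiman_crocodilus;",
    "   tree gen.1 = [&U] (1,2,(3,4));",
    "   tree gen.2 = [&U] (1,3,(2,4));",
    "end;"), ".t")
}

nexus_matrix_fixture <- function(interleave = FALSE) {
  if (!interleave) {
    write_lines_tmp(c(
      "#NEXUS",
      "BEGIN DATA;",
      "  DIMENSIONS NTAX=4 NCHAR=6;",
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
      "  MATRIX",
      "    taxA ?01?10",
      "    taxB 0-1101",
      "    taxC 010101",
      "    taxD ??-?10",
      "  ;",
      "END;"), ".nex")
  } else {
    write_lines_tmp(c(
      "#NEXUS",
      "BEGIN DATA;",
      "  DIMENSIONS NTAX=4 NCHAR=6;",
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=- INTERLEAVE=YES;",
      "  MATRIX",
      "    taxA ?01",
      "    taxB 0-1",
      "    taxC 010",
      "    taxD ??-",
      "    taxA ?10",
      "    taxB 101",
      "    taxC 101",
      "    taxD ?10",
      "  ;",
      "END;"), ".nex")
  }
}

cli_path <- function() system.file("cli", "tii.R", package = "tii")

run_cli <- function(args) {
  out <- tempfile()
  err <- tempfile()
  status <- system2("Rscript", c(cli_path(), args), stdout = out,
                    stderr = err)
  list(status = status,
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
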