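test_that("parse_smiles handles chains, aromatics, brackets, and errors", {
  m <- parse_smiles("CCO")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$element, c("C", "C", "O"))
  expect_equal(nrow(m$bonds), 2)
  expect_true(all(m$bonds$order == "-"))

  b <- parse_smiles("c1ccccc1")
  expect_equal(nrow(b$atoms), 6)
  expect_true(all(b$atoms$aromatic))
  expect_equal(nrow(b$bonds), 6)
  expect_true(all(b$bonds$order == ":"))
  expect_true(all(b$atoms$in_ring))

  br <- parse_smiles("C[NH3+]")
  expect_equal(br$atoms$charge, c(0L, 1L))
  expect_equal(parse_smiles("CC(=O)[O-]")$atoms$charge[4], -1L)

  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(C"), "parentheses")
  expect_error(parse_smiles("C)C"), "parentheses")
  expect_error(parse_smiles("CQ"), "unexpected character")
  expect_error(parse_smiles("C[C@H](N)O"), "stereo")
  expect_error(parse_smiles("C/C=C/C"), "stereo")
})

test_that("every built-in panel molecule parses and has the stated features", {
  panel <- gen_molecules()
  expect_gte(length(panel), 10)
  mols <- lapply(panel, parse_smiles)
  expect_true(all(vapply(mols, inherits, logical(1), "mol_graph")))
  n_aromatic <- vapply(mols, function(m) sum(m$atoms$aromatic), integer(1))
  expect_true(any(n_aromatic >= 6))
  hetero <- vapply(mols, function(m) any(!m$atoms$element %in% "C"), logical(1))
  expect_true(any(hetero))
})

test_that("path enumeration matches exhaustive expectations", {
  expect_equal(enumerate_paths(parse_smiles("C")), "C")
  expect_setequal(unique(enumerate_paths(parse_smiles("CCC"))),
                  c("C", "C-C", "C-C-C"))
  expect_setequal(unique(enumerate_paths(parse_smiles("c1ccccc1"))),
                  c("c", "c:c", "c:c:c", "c:c:c:c", "c:c:c:c:c",
                    "c:c:c:c:c:c"))
  # max_atoms truncation
  expect_setequal(unique(enumerate_paths(parse_smiles("CCCC"), max_atoms = 2)),
                  c("C", "C-C"))
})

test_that("sphere enumeration: single atoms, symmetry, benzene collapse", {
  expect_length(unique(enumerate_spheres(parse_smiles("C"))), 1)
  eth <- enumerate_spheres(parse_smiles("CC"))
  by_atom <- matrix(eth, nrow = 5)   # radii 1..5 per atom
  expect_identical(by_atom[, 1], by_atom[, 2])
  benz <- enumerate_spheres(parse_smiles("c1ccccc1"))
  expect_lte(length(unique(benz)), 5)
})

test_that("fingerprints are invariant under atom relabeling", {
  withr::with_seed(99, {
    for (smi in gen_molecules()[c("anatabine_like", "toluene", "acetamide")]) {
      m <- parse_smiles(smi)
      fp_p <- path_fingerprint(m)$bits
      fp_s <- sphere_fingerprint(m)$bits
      for (i in 1:25) {
        r <- relabel_mol(m)
        expect_identical(path_fingerprint(r)$bits, fp_p)
        expect_identical(sphere_fingerprint(r)$bits, fp_s)
      }
    }
  })
})

test_that("ethane path bits are a subset of propane's (substructure)", {
  fp2 <- path_fingerprint(parse_smiles("CC"))
  fp3 <- path_fingerprint(parse_smiles("CCC"))
  expect_true(all(which(fp2$bits) %in% which(fp3$bits)))
  expect_true(any(path_fingerprint(parse_smiles("C"))$bits))
  expect_false(identical(sphere_fingerprint(parse_smiles("C"))$bits,
                         sphere_fingerprint(parse_smiles("CC"))$bits))
})

test_that("hashed bit positions are stable across runs (golden values)", {
  # frozen from an independent FNV-1a 64-bit implementation
  expect_equal(sort(which(path_fingerprint(parse_smiles("c1ccccc1"))$bits)),
               c(91, 150, 218, 263, 450, 499))
  expect_equal(sort(which(path_fingerprint(parse_smiles("CCO"))$bits)),
               c(75, 83, 191, 287, 487))
})

test_that("sphere fingerprint is hash-transparent", {
  benz <- parse_smiles("c1ccccc1")
  pyr <- parse_smiles("c1ccncc1")
  fb <- sphere_fingerprint(benz)$bits
  fp <- sphere_fingerprint(pyr)$bits
  # map explicit fragment sets through the hash and compare Tanimoto
  hb <- unique(sysphar:::cpp_hash_bits(unique(enumerate_spheres(benz)), 512L))
  hp <- unique(sysphar:::cpp_hash_bits(unique(enumerate_spheres(pyr)), 512L))
  t_fp <- sum(fb & fp) / sum(fb | fp)
  t_hash <- length(intersect(hb, hp)) / length(union(hb, hp))
  expect_equal(t_fp, t_hash, tolerance = 1e-15)
})

test_that("frag_fingerprint flags exactly the dictionary fragments present", {
  expect_false(any(frag_fingerprint(parse_smiles("C"), "C-C")$bits))
  expect_true(frag_fingerprint(parse_smiles("CC"), "C-C")$bits[1])
  expect_error(frag_fingerprint(parse_smiles("CC"), rep("x", 600)),
               "dictionary larger")
  dict <- default_fragment_dictionary()
  expect_lte(length(dict), 512)
  for (smi in gen_molecules()[c("ethanol", "phenol")]) {
    m <- parse_smiles(smi)
    fp <- frag_fingerprint(m, dict)
    present <- dict %in% unique(c(enumerate_paths(m), enumerate_spheres(m)))
    expect_identical(fp$bits[seq_along(dict)], present)
  }
})

test_that("tanimoto: identities, disjoint sets, hand count, and errors", {
  mk <- function(pos) {
    b <- rep(FALSE, 512); b[pos] <- TRUE
    sysphar:::new_fingerprint(b, "PathFp", 512L)
  }
  expect_equal(tanimoto(mk(1:3), mk(1:3)), 1)
  expect_equal(tanimoto(mk(1:3), mk(4:6)), 0)
  expect_equal(tanimoto(mk(1:3), mk(2:4)), 0.5)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 1)
  expect_equal(tanimoto_distance(mk(1:3), mk(2:4)), 0.5)
  sph <- sysphar:::new_fingerprint(rep(FALSE, 512), "SphereFp", 512L)
  expect_error(tanimoto(mk(1), sph), "descriptor mismatch")
})

test_that("tanimoto distance satisfies the triangle inequality (property)", {
  withr::with_seed(17, {
    fps <- lapply(1:30, function(i)
      sysphar:::new_fingerprint(runif(64) < 0.3, "PathFp", 64L))
    for (i in 1:200) {
      abc <- sample(30, 3)
      dab <- tanimoto_distance(fps[[abc[1]]], fps[[abc[2]]])
      dbc <- tanimoto_distance(fps[[abc[2]]], fps[[abc[3]]])
      dac <- tanimoto_distance(fps[[abc[1]]], fps[[abc[3]]])
      expect_lte(dac, dab + dbc + 1e-12)
    }
  })
})

test_that("similarity_matrix: self row of zeros, dimensions, near-duplicates", {
  panel <- gen_molecules()
  mols <- lapply(panel, parse_smiles)
  sm <- similarity_matrix(mols, mols$anatabine_like)
  expect_equal(dim(sm), c(length(panel), 4))
  expect_equal(unlist(sm[sm$molecule == "anatabine_like", -1]),
               c(PathFp = 0, SphereFp = 0, FragFP = 0))
  # planted near-duplicate pair beats every cross-pair in every descriptor
  sm_nic <- similarity_matrix(mols, mols$nicotine_like)
  d_pair <- sm_nic[sm_nic$molecule == "nornicotine_like", -1]
  others <- sm_nic[!sm_nic$molecule %in% c("nicotine_like", "nornicotine_like"), -1]
  for (d in names(d_pair)) expect_true(all(others[[d]] > d_pair[[d]]))
})

test_that("SMILES file round trip", {
  path <- withr::local_tempfile(fileext = ".smi")
  write_smiles_file(gen_molecules(), path)
  back <- read_smiles_file(path)
  expect_identical(back, gen_molecules())
})
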