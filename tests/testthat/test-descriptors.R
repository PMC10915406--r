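test_that("composition descriptors match hand-computed fractions and normalize", {
  a <- aac_descriptor("AAAA")
  expect_equal(unname(a["AAC.A"]), 1)
  expect_equal(sum(a), 1)

  a2 <- aac_descriptor("ACDE")
  expect_equal(unname(a2[c("AAC.A", "AAC.C", "AAC.D", "AAC.E")]), rep(0.25, 4))

  # X residues are excluded from numerator and denominator
  expect_equal(aac_descriptor("AXA"), aac_descriptor("AA"))
  expect_error(aac_descriptor("XXX"), class = "eciml_degenerate_sequence")

  g <- gaac_descriptor("GAVLMI")
  expect_equal(unname(g["GAAC.aliphatic"]), 1)
  expect_equal(unname(gaac_descriptor("DE")["GAAC.negative"]), 1)
  kd <- gaac_descriptor("KD")
  expect_equal(unname(kd[c("GAAC.positive", "GAAC.negative")]), c(0.5, 0.5))

  d <- gdpc_descriptor("DE")
  expect_equal(unname(d["GDPC.negative.negative"]), 1)
  kdkd <- gdpc_descriptor("KDKD")
  expect_equal(unname(kdkd["GDPC.positive.negative"]), 2 / 3)
  expect_equal(unname(kdkd["GDPC.negative.positive"]), 1 / 3)
  expect_error(gdpc_descriptor("K"), class = "eciml_degenerate_sequence")

  set.seed(4)
  for (i in 1:5) {
    s <- random_peptide(sample(10:60, 1))
    expect_equal(sum(aac_descriptor(s)), 1, tolerance = 1e-12)
    expect_equal(sum(gaac_descriptor(s)), 1, tolerance = 1e-12)
    expect_equal(sum(gdpc_descriptor(s)), 1, tolerance = 1e-12)
  }
})

test_that("sequence tables have the advertised dimensions and determinism", {
  set.seed(8)
  seqs <- setNames(c(random_peptide(30), random_peptide(30)), c("a", "b"))
  seqs <- c(seqs, c = unname(seqs["a"]))  # duplicate sequence
  for (kind in c("aac", "gaac", "gdpc", "composition50")) {
    tab <- build_sequence_table(seqs, descriptor_spec(kind))
    d_expected <- c(aac = 20L, gaac = 5L, gdpc = 25L, composition50 = 50L)[[kind]]
    expect_equal(dim(tab$vectors), c(3L, d_expected))
    expect_identical(tab$provenance, "regular")
  }
  tab <- build_sequence_table(seqs, descriptor_spec("composition50"))
  expect_equal(tab$vectors["a", ], tab$vectors["c", ])
})

test_that("external descriptor tables align to the dataset order and flag missing ids", {
  v <- matrix(1:6, 3, 2, dimnames = list(c("b", "a", "c"), NULL))
  tab <- build_sequence_table(setNames(c("MK", "ML", "MA"), c("a", "b", "c")),
                              descriptor_spec("external", vectors = v))
  expect_equal(tab$object_ids, c("a", "b", "c"))
  expect_equal(unname(tab$vectors["a", ]), unname(v["a", ]))

  expect_error(
    build_sequence_table(setNames("MK", "zz"),
                         descriptor_spec("external", vectors = v)),
    class = "eciml_alignment_error")

  # CSV path route
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(object_id = c("a", "b"), d1 = c(1, 2), d2 = c(3, 4)),
            f, row.names = FALSE)
  tab2 <- build_chemical_table(NULL, descriptor_spec("external", path = f),
                               object_ids = c("b", "a"))
  expect_equal(unname(tab2$vectors[, 1]), c(2, 1))
})

test_that("chemical tables: fingerprints are 0/1 of full width, physchem is sane", {
  smiles <- setNames(c("C", "CCO", "CCO"), c("methane", "eth1", "eth2"))
  fp <- build_chemical_table(smiles, descriptor_spec("chem_fingerprint"))
  expect_equal(ncol(fp$vectors), 2048L)
  expect_true(all(fp$vectors %in% c(0, 1)))
  expect_equal(fp$vectors["eth1", ], fp$vectors["eth2", ])

  pc <- build_chemical_table(smiles, descriptor_spec("chem_physchem"))
  expect_equal(pc$vectors["methane", "heavy_atoms"], 1)
  expect_equal(pc$vectors["methane", "hbd"], 0)
  expect_equal(pc$vectors["eth1", "heavy_atoms"], 3)
  expect_equal(pc$vectors["eth1", "rings"], 0)
  benz <- build_chemical_table(c(b = "c1ccccc1"), descriptor_spec("chem_physchem"))
  expect_equal(benz$vectors["b", "rings"], 1)
  expect_equal(benz$vectors["b", "rotatable_bonds"], 0)

  expect_error(build_chemical_table(c(bad = "xx(("), descriptor_spec("chem_fingerprint")),
               class = "eciml_parse_error")
})

test_that("shuffling preserves composition and length but destroys order", {
  set.seed(21)
  seqs <- setNames(replicate(3, random_peptide(60)), c("a", "b", "c"))
  sh <- shuffle_sequences(seqs, seed = 5)
  expect_equal(nchar(sh), nchar(seqs))
  for (id in names(seqs)) {
    expect_equal(aac_descriptor(sh[[id]]), aac_descriptor(seqs[[id]]))
    expect_equal(gaac_descriptor(sh[[id]]), gaac_descriptor(seqs[[id]]))
  }
  # order information is gone: GDPC generally differs on a long sequence
  expect_false(isTRUE(all.equal(gdpc_descriptor(sh[["a"]]),
                                gdpc_descriptor(seqs[["a"]]))))
  expect_identical(shuffle_sequences(seqs, seed = 5), sh)
  expect_false(identical(shuffle_sequences(seqs, seed = 6), sh))
})

test_that("permutation reassigns rows bijectively, reproducibly, conservatively", {
  set.seed(31)
  tab <- descriptor_table(paste0("o", 1:6), matrix(rnorm(12), 6), "test")
  p1 <- permute_table(tab, seed = 9)
  expect_identical(p1$provenance, "permuted")
  expect_identical(p1$object_ids, tab$object_ids)
  # multiset of vectors preserved
  srt <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(unname(srt(p1$vectors)), unname(srt(tab$vectors)))
  expect_equal(permute_table(tab, seed = 9)$vectors, p1$vectors)

  # applying the inverse permutation restores the table
  perm <- match(apply(p1$vectors, 1, paste, collapse = ","),
                apply(tab$vectors, 1, paste, collapse = ","))
  expect_equal(unname(p1$vectors[order(perm), ]), unname(tab$vectors))

  one <- descriptor_table("solo", matrix(1:3, 1), "test")
  expect_equal(permute_table(one, seed = 1)$vectors, one$vectors)
})

test_that("pair feature concatenation lays out enzyme block then chemical block", {
  et <- descriptor_table(c("e1", "e2"), matrix(c(1, 2, 3, 4), 2), "enz")
  ct <- descriptor_table(c("c1", "c2"), matrix(c(10, 20, 30, 40), 2), "chem")
  pairs <- data.frame(enzyme_id = c("e1", "e2", "e1"),
                      chemical_id = c("c1", "c1", "c2"))
  x <- concat_pair_features(et, ct, pairs)
  expect_equal(dim(x), c(3L, 4L))
  expect_equal(unname(x[1, ]), c(1, 3, 10, 30))
  expect_equal(unname(x[2, ]), c(2, 4, 10, 30))
  # shared enzyme gives identical enzyme blocks
  expect_equal(unname(x[1, 1:2]), unname(x[3, 1:2]))

  empty <- concat_pair_features(et, ct, pairs[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 4L)

  expect_error(concat_pair_features(et, ct, data.frame(enzyme_id = "zz", chemical_id = "c1")),
               class = "eciml_lookup_error")
})
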