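# Molecule parsing/cleaning, descriptors, fingerprints, Murcko frameworks.

test_that("parse_and_clean enforces range, validity and uniqueness", {
  recs <- data.frame(
    id = c("hot", "ok", "bad", "dup"),
    smiles = c("CCO", "c1ccccc1", "C1CC", "OCC"),
    activity = c(7.5, 2.0, 3.0, 2.5),
    stringsAsFactors = FALSE)
  out <- parse_and_clean(recs, 0, 7)
  # "dup" survives: the molecule it duplicates ("hot") was itself rejected
  expect_equal(out$molecules$id, c("ok", "dup"))
  expect_equal(out$molecules$smiles[1], canonical_smiles("c1ccccc1"))
  rej <- out$rejections
  expect_equal(rej$reason[rej$id == "hot"], "activity_range")
  expect_equal(rej$reason[rej$id == "bad"], "parse_fail")
  # with both ethanol records in range, the second is the duplicate
  recs2 <- data.frame(id = c("a", "b"), smiles = c("CCO", "OCC"),
                      activity = c(2, 3), stringsAsFactors = FALSE)
  out2 <- parse_and_clean(recs2)
  expect_equal(out2$molecules$id, "a")
  expect_equal(out2$rejections$reason, "duplicate")
  expect_error(parse_and_clean(recs[0, ]), "non-empty")
  expect_error(parse_and_clean(
    data.frame(id = "x", smiles = "C1CC", activity = 2)), "all records")
})

test_that("descriptor examples match known molecular facts", {
  D <- compute_descriptors(c("CCO", "CC", "c1ccccc1"),
                           c("MW", "b_rotN", "a_acc"))
  expect_lt(abs(unname(D[1, "MW"]) - 46.07), 0.01)
  expect_equal(unname(D[2, "b_rotN"]), 0)      # ethane: no rotatable bonds
  expect_equal(unname(D[3, "a_acc"]), 0)       # benzene: no acceptors
  expect_error(compute_descriptors("CCO", "nonsense"), "unknown descriptor")
})

test_that("descriptors agree exactly after a canonical-SMILES round-trip", {
  smis <- c("c1ccc(cc1)C(F)(F)F", "CC(=O)Nc1ccc(O)cc1", "C1CCCCC1CN")
  can <- canonical_smiles(smis)
  D1 <- compute_descriptors(smis)
  D2 <- compute_descriptors(can)
  expect_equal(unname(D1), unname(D2))
})

test_that("fingerprint bits fire on their defining substructures", {
  pub <- load_fingerprint_dictionary("pubchem")
  sub <- load_fingerprint_dictionary("substructure")
  fp_pub <- compute_fingerprint(c("c1ccncc1", "C"), pub)
  expect_equal(unname(fp_pub[1, "PubchemFP14"]), 1L)  # pyridine: N >= 1
  expect_equal(unname(fp_pub[2, "PubchemFP14"]), 0L)
  fp_sub <- compute_fingerprint(c("FC(F)(F)c1ccccc1", "C"), sub)
  expect_equal(unname(fp_sub[1, "SubFP294"]), 1L)     # trifluoromethyl
  # methane carries none of the alert bits
  expect_equal(unname(fp_sub[2, c("SubFP294", "SubFP9", "SubFP179",
                                  "SubFP275")]),
               rep(0L, 4))
  expect_true(all(fp_sub %in% c(0L, 1L)))
  expect_equal(ncol(fp_sub), nrow(sub))
})

test_that("fingerprints are invariant to SMILES atom-order permutation", {
  sub <- load_fingerprint_dictionary("substructure")
  pairs <- rbind(c("c1ccccc1C(F)(F)F", "FC(F)(F)c1ccccc1"),
                 c("CC(=O)Nc1ccc(O)cc1", "Oc1ccc(NC(C)=O)cc1"),
                 c("c1ccncc1CN", "NCc1ccncc1"))
  for (i in seq_len(nrow(pairs))) {
    f <- compute_fingerprint(pairs[i, ], sub)
    expect_equal(f[1, ], f[2, ])
  }
})

test_that("dictionary files parse, compile and reject malformed input", {
  sub <- load_fingerprint_dictionary("substructure")
  expect_s3_class(sub, "fp_dictionary")
  expect_equal(sub$bit, seq_len(nrow(sub)) - 1L)
  expect_true(all(sub$type %in% c("smarts", "count")))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("0\t[#6]\tcarbon", "2\t[#7]\tskip-a-bit"), bad)
  expect_error(read_fingerprint_dictionary(bad), "contiguous")
  bad2 <- tempfile(fileext = ".tsv")
  writeLines("0\t[#6](((\tbroken", bad2)
  expect_error(read_fingerprint_dictionary(bad2), "compile")
  unlink(c(bad, bad2))
})

test_that("count rules threshold on element counts", {
  pub <- load_fingerprint_dictionary("pubchem")
  fp <- compute_fingerprint(c("N#N", "NCCN", "C"), pub)
  # NCCN has two nitrogens: N>=1 and N>=2 fire, N>=4 does not
  expect_equal(unname(fp[2, c("PubchemFP14", "PubchemFP15", "pubchem002")]),
               c(1L, 1L, 0L))
})

test_that("Murcko frameworks strip side chains and are idempotent", {
  mf <- murcko_framework(c("Cc1ccccc1", "CCCCCC", "c1ccccc1Cc1ccccc1"))
  expect_equal(mf[1], canonical_smiles("c1ccccc1"))
  expect_equal(mf[2], "")
  # diphenylmethane keeps both rings and the one-carbon linker
  expect_equal(mf[3], canonical_smiles("c1ccccc1Cc1ccccc1"))
  # idempotence
  mf2 <- murcko_framework(mf[c(1, 3)])
  expect_equal(mf2, mf[c(1, 3)])
  # oracle: pruned atom set of toluene is exactly the ring
  # (edges of hydrogen-suppressed toluene: methyl carbon is atom 1)
  edges <- cbind(c(1, 2, 3, 4, 5, 6, 7), c(2, 3, 4, 5, 6, 7, 2))
  expect_equal(oracle_two_core(edges, 7), 2:7)
})

test_that("exocyclic double-bond atoms stay on the framework", {
  # benzophenone: framework keeps the carbonyl oxygen
  mf <- murcko_framework("O=C(c1ccccc1)c1ccccc1")
  expect_equal(mf, canonical_smiles("O=C(c1ccccc1)c1ccccc1"))
  # acetophenone: the whole acetyl group is a side chain
  expect_equal(murcko_framework("CC(=O)c1ccccc1"),
               canonical_smiles("c1ccccc1"))
})
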