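test_that("rule-based tokenisation splits on punctuation but keeps decimals and hyphens", {
  expect_identical(tokenizeField(""), character())
  expect_identical(tokenizeField("Clearance was 5.2 L/h."),
                   c("Clearance", "was", "5.2", "L", "/", "h", "."))
  expect_identical(tokenizeField("half-life"), "half-life")
  expect_identical(tokenizeField("AUC(0-24) = 41 mg*h/L"),
                   c("AUC", "(", "0-24", ")", "=", "41", "mg", "*", "h",
                     "/", "L"))
  # all non-whitespace characters are recovered by concatenation
  for (s in c("Vd was 0.2 L/kg (95% CI).", "t1/2: 3.1h", "a,b;c"))
    expect_identical(paste(tokenizeField(s), collapse = ""),
                     gsub("[[:space:]]", "", s))
})

test_that("Porter stemmer matches the algorithm's published behaviour", {
  pairs <- c(
    caresses = "caress", ponies = "poni", ties = "ti", caress = "caress",
    cats = "cat", feed = "feed", agreed = "agre", plastered = "plaster",
    bled = "bled", motoring = "motor", sing = "sing", conflated = "conflat",
    troubled = "troubl", sized = "size", hopping = "hop", tanned = "tan",
    falling = "fall", hissing = "hiss", fizzed = "fizz", failing = "fail",
    filing = "file", happy = "happi", sky = "sky", relational = "relat",
    conditional = "condit", rational = "ration", valenci = "valenc",
    hesitanci = "hesit", digitizer = "digit", conformabli = "conform",
    radicalli = "radic", differentli = "differ", vileli = "vile",
    analogousli = "analog", vietnamization = "vietnam",
    predication = "predic", operator = "oper", feudalism = "feudal",
    decisiveness = "decis", hopefulness = "hope", callousness = "callous",
    formaliti = "formal", sensitiviti = "sensit", sensibiliti = "sensibl",
    triplicate = "triplic", formative = "form", formalize = "formal",
    electriciti = "electr", electrical = "electr", hopeful = "hope",
    goodness = "good", revival = "reviv", allowance = "allow",
    inference = "infer", airliner = "airlin", gyroscopic = "gyroscop",
    adjustable = "adjust", defensible = "defens", irritant = "irrit",
    replacement = "replac", adjustment = "adjust", dependent = "depend",
    adoption = "adopt", communism = "commun", activate = "activ",
    angulariti = "angular", homologous = "homolog", effective = "effect",
    bowdlerize = "bowdler", probate = "probat", rate = "rate",
    cease = "ceas", controll = "control", roll = "roll",
    clearance = "clearanc", pharmacokinetics = "pharmacokinet",
    estimated = "estim", bioavailability = "bioavail")
  expect_identical(porterStem(names(pairs)), unname(pairs))
})

test_that("chemical detection finds single and multi-token lexicon entries", {
  expect_identical(
    detectChemicals(c("midazolam", "clearance"), "midazolam"),
    matrix(c(1L, 1L), 1, 2, dimnames = list(NULL, c("start", "end"))))
  expect_identical(nrow(detectChemicals(c("a", "b"), character())), 0L)
  toks <- c("oral", "valproic", "acid", "dosing")
  spans <- detectChemicals(toks, c("valproic acid", "acid"))
  expect_identical(unname(spans[1, ]), c(2L, 3L))  # longest match wins
  expect_identical(nrow(spans), 1L)
  # case-insensitive
  expect_identical(nrow(detectChemicals(c("Midazolam"), "midazolam")), 1L)
})

test_that("entity masking replaces each span by exactly one mask token", {
  expect_identical(maskEntities(c("a", "midazolam", "b"),
                                cbind(start = 2L, end = 2L)),
                   c("a", "@CHEM", "b"))
  toks <- c("x", "y")
  expect_identical(maskEntities(toks, detectChemicals(toks, character())),
                   toks)
  expect_identical(maskEntities(c("valproic", "acid"),
                                cbind(start = 1L, end = 2L)), "@CHEM")
  expect_error(maskEntities(c("a", "b", "c"),
                            rbind(c(1L, 2L), c(2L, 3L))), "overlap")
  expect_error(maskEntities(c("a"), cbind(start = 1L, end = 2L)), "bounds")
})

test_that("token normalisation applies the documented stage order", {
  sw <- pkStopwords()
  # all-digit tokens -> ## after punctuation stripping, so 3.5 -> 35 -> ##
  expect_identical(normalizeTokens("123", sw), "##")
  expect_identical(normalizeTokens("3.5", sw), "##")
  expect_identical(normalizeTokens("3.5", sw, maskDecimals = FALSE), "35")
  # stopwords dropped, punctuation stripped inside tokens, stems applied
  expect_identical(normalizeTokens(c("the", "Clearance,"), sw), "clearanc")
  # pure punctuation tokens vanish
  expect_identical(normalizeTokens(c(".", "/", "(", ")"), sw), character())
  # mask tokens are exempt from every transformation
  expect_identical(normalizeTokens(c("@CHEM", "##", "Dosing"), sw),
                   c("@CHEM", "##", "dose"))
  expect_identical(normalizeTokens(character(), sw), character())
})

test_that("normalisation without stemming is idempotent", {
  set.seed(11)
  sw <- pkStopwords()
  pool <- c("The", "Clearance,", "5.2", "half-life", "was", "@CHEM",
            "(AUC)", "0-24", "patients", "I", "mg/kg", "##", "a", "B2")
  for (rep in 1:25) {
    toks <- sample(pool, sample(1:10, 1), replace = TRUE)
    once <- normalizeTokens(toks, sw, stem = FALSE)
    twice <- normalizeTokens(once, sw, stem = FALSE)
    expect_identical(twice, once)
  }
})

test_that("normalised output has no uppercase, no internal punctuation, no bare digits", {
  set.seed(12)
  sw <- pkStopwords()
  for (rep in 1:25) {
    txt <- paste(sample(c("AUC", "10", "3.5", "Half-Life", "the", "(CL)",
                          "was", "estimated", "9.81", "mg", "NONMEM"),
                        sample(3:11, 1), replace = TRUE), collapse = " ")
    out <- normalizeTokens(tokenizeField(txt), sw)
    plain <- setdiff(out, c("##", "@CHEM"))
    expect_false(any(grepl("[[:upper:]]", plain)))
    expect_false(any(grepl("[[:punct:]]", plain)))
    expect_false(any(grepl("^[0-9]+$", plain)))
  }
})

test_that("masking preserves token count minus span shrinkage", {
  toks <- tokenizeField("oral valproic acid and midazolam pharmacokinetics")
  spans <- detectChemicals(toks, pkChemicalLexicon())
  masked <- maskEntities(toks, spans)
  widths <- spans[, "end"] - spans[, "start"] + 1L
  expect_identical(length(masked),
                   length(toks) - sum(widths) + nrow(spans))
  expect_identical(sum(masked == "@CHEM"), nrow(spans))
})
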