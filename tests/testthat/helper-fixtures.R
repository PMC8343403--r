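# Fixtures built in code: a tiny hand-written corpus and shortcuts used
# across the test files.

miniXmlPath <- function() {
  system.file("extdata", "mini_medline.xml", package = "pkTriage")
}

tinyCorpus <- function() {
  DocumentCorpus(
    pmid = c("1", "2", "3"),
    title = c("Pharmacokinetics of drug X in rats",
              "A review of something else",
              "Clearance of midazolam in children"),
    abstract = c("Clearance was 5.2 L/h.",
                 "",
                 "Volume of distribution was 0.2 L/kg; half-life 3 h."),
    journal = c("Clin Pharmacokinet", "Misc Rev", "Clin Pharmacokinet"),
    publicationTypes = list("Journal Article", "Review", "Journal Article"),
    meshTerms = list(c("Pharmacokinetics", "Rats"), character(),
                     "Midazolam"),
    chemicals = list("midazolam", character(), "midazolam"))
}

# separable feature matrix: one informative column, the rest noise
separableFeatures <- function(n = 120, prevalence = 0.25, seed = 42) {
  set.seed(seed)
  y <- rep(c("Relevant", "NotRelevant"),
           c(round(n * prevalence), n - round(n * prevalence)))
  y <- sample(y)
  x <- cbind(signal = ifelse(y == "Relevant", 1, 0) + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  rownames(x) <- as.character(seq_len(n))
  list(x = x, y = factor(y, levels = labelLevels()))
}

fastConfig <- function(...) {
  boosterConfig(maxRounds = 60L, patience = 10L, ...)
}
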