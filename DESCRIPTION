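Package: meiochip
Title: ChIP-Seq Profile Analysis at Meiotic DSB Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multi-mapping-aware ChIP-seq coverage profiles for
    compact genomes, smooths them with a Nadaraya-Watson kernel, normalizes
    tagged samples against untagged controls with the NCIS background-fraction
    estimator, calls peaks by valley-flanked (topographic-prominence)
    criteria, matches peaks across profiles within the smoothing bandwidth
    and compares their heights by Pearson correlation, groups Spo11-oligo
    5'-ends into DSB hotspots, and attaches hypergeometric and binomial
    significance to peak/peak and peak/hotspot co-localization. Includes a
    seeded synthetic-data generator that emulates the assumed data model
    (background plus localized peaks at hotspot positions, multi-mapping
    reads, paired profiles with a target peak-height correlation) so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
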