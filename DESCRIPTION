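Package: implantpath
Title: Implant Pathway Derivation from Oriented Tooth Bounding Boxes on Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for deriving dental implant placement pathways in single-tooth
    edentulous gaps on panoramic radiographs. Given oriented bounding boxes (OBBs)
    of the two adjacent teeth, the pathway is constructed by extending auxiliary
    lines along the gap-facing OBB edges and taking their internal angle bisector
    in implicit-line form. Includes the companion image-enhancement stack
    (bilateral filtering, histogram equalization, weighted compositing,
    brightness/exposure/noise augmentation), detection evaluation (rotated IoU,
    precision/recall/accuracy, mAP50, angular-deviation reports), readers and
    writers for normalized OBB/HBB label text formats and pathway JSON, an
    overlay renderer, and a synthetic radiograph-like scene generator with
    analytic ground truth so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    jsonlite,
    png,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
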