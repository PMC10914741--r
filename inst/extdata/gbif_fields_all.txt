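gbifID
datasetKey
occurrenceID
kingdom
phylum
class
order
family
genus
species
infraspecificEpithet
taxonRank
scientificName
verbatimScientificName
verbatimScientificNameAuthorship
countryCode
locality
municipality
county
stateProvince
occurrenceStatus
individualCount
publishingOrgKey
decimalLatitude
decimalLongitude
coordinateUncertaintyInMeters
coordinatePrecision
elevation
elevationAccuracy
depth
depthAccuracy
eventDate
day
month
year
taxonKey
speciesKey
basisOfRecord
institutionCode
collectionCode
catalogNumber
recordNumber
identifiedBy
dateIdentified
license
rightsHolder
recordedBy
typeStatus
establishmentMeans
lastInterpreted
mediaType
fieldNotes
habitat
issue
type
modified
language
accessRights
bibliographicCitation
references
institutionID
collectionID
datasetID
datasetName
ownerInstitutionCode
informationWithheld
dataGeneralizations
dynamicProperties
recordedByID
organismQuantity
organismQuantityType
sex
lifeStage
reproductiveCondition
behavior
degreeOfEstablishment
pathway
georeferenceVerificationStatus
preparations
disposition
associatedMedia
associatedOccurrences
associatedReferences
associatedSequences
associatedTaxa
otherCatalogNumbers
occurrenceRemarks
organismID
organismName
organismScope
associatedOrganisms
previousIdentifications
organismRemarks
materialSampleID
eventID
parentEventID
fieldNumber
eventTime
startDayOfYear
endDayOfYear
verbatimEventDate
samplingProtocol
sampleSizeValue
sampleSizeUnit
samplingEffort
eventRemarks
locationID
higherGeographyID
higherGeography
continent
waterBody
islandGroup
island
country
verbatimLocality
minimumElevationInMeters
maximumElevationInMeters
verbatimElevation
minimumDepthInMeters
maximumDepthInMeters
verbatimDepth
minimumDistanceAboveSurfaceInMeters
maximumDistanceAboveSurfaceInMeters
locationAccordingTo
locationRemarks
geodeticDatum
pointRadiusSpatialFit
verbatimCoordinates
verbatimLatitude
verbatimLongitude
verbatimCoordinateSystem
verbatimSRS
footprintWKT
footprintSRS
footprintSpatialFit
georeferencedBy
georeferencedDate
georeferenceProtocol
georeferenceSources
georeferenceRemarks
geologicalContextID
earliestEonOrLowestEonothem
latestEonOrHighestEonothem
earliestEraOrLowestErathem
latestEraOrHighestErathem
earliestPeriodOrLowestSystem
latestPeriodOrHighestSystem
earliestEpochOrLowestSeries
latestEpochOrHighestSeries
earliestAgeOrLowestStage
latestAgeOrHighestStage
lowestBiostratigraphicZone
highestBiostratigraphicZone
lithostratigraphicTerms
group
formation
member
bed
identificationID
verbatimIdentification
identificationQualifier
identifiedByID
identificationReferences
identificationVerificationStatus
identificationRemarks
taxonID
scientificNameID
acceptedNameUsageID
parentNameUsageID
originalNameUsageID
nameAccordingToID
namePublishedInID
taxonConceptID
acceptedNameUsage
parentNameUsage
originalNameUsage
nameAccordingTo
namePublishedIn
namePublishedInYear
higherClassification
superfamily
subfamily
genericName
subgenus
infragenericEpithet
specificEpithet
cultivarEpithet
verbatimTaxonRank
scientificNameAuthorship
vernacularName
nomenclaturalCode
taxonomicStatus
nomenclaturalStatus
taxonRemarks
acceptedTaxonKey
kingdomKey
phylumKey
classKey
orderKey
familyKey
genusKey
subgenusKey
acceptedScientificName
lastParsed
lastCrawled
distanceFromCentroidInMeters
hasCoordinate
hasGeospatialIssues
repatriated
level0Gid
level0Name
level1Gid
level1Name
level2Gid
level2Name
level3Gid
level3Name
gadm
projectId
programmeAcronym
protocol
publishingCountry
crawlId
datasetPublishingCountry
isSequenced
isInCluster
datasetLicense
recordedByIDType
identifiedByIDType
dnaSequenceID
gbifRegion
publishedByGbifRegion
institutionKey
collectionKey
networkKeys
depthAccuracyVerbatim
elevationAccuracyVerbatim
eventType
vitality
caste
verticalDatum
typifiedName
tribe
subtribe
superorder
suborder
infraorder
subclass
infraclass
subphylum
subkingdom
cohort
parvorder
megaclass
section
subsection
series
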