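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
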