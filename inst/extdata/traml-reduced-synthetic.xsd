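<?xml version="1.0" encoding="UTF-8"?>
<!-- Reduced, offline-authored (synthetic) subset of the TraML 1.0.0 schema
     covering the element structure written by this toolkit: cvList,
     CompoundList/Peptide with retention-time cvParams, and TransitionList
     with Precursor/Product m/z and intensity cvParams. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           xmlns:tml="http://psi.hupo.org/ms/traml"
           targetNamespace="http://psi.hupo.org/ms/traml"
           elementFormDefault="qualified">

  <xs:complexType name="cvParamType">
    <xs:attribute name="cvRef" type="xs:string" use="required"/>
    <xs:attribute name="accession" type="xs:string" use="required"/>
    <xs:attribute name="name" type="xs:string" use="required"/>
    <xs:attribute name="value" type="xs:string"/>
    <xs:attribute name="unitCvRef" type="xs:string"/>
    <xs:attribute name="unitAccession" type="xs:string"/>
    <xs:attribute name="unitName" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="cvType">
    <xs:attribute name="id" type="xs:string" use="required"/>
    <xs:attribute name="fullName" type="xs:string" use="required"/>
    <xs:attribute name="version" type="xs:string"/>
    <xs:attribute name="URI" type="xs:anyURI" use="required"/>
  </xs:complexType>

  <xs:complexType name="retentionTimeType">
    <xs:sequence>
      <xs:element name="cvParam" type="tml:cvParamType" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="retentionTimeListType">
    <xs:sequence>
      <xs:element name="RetentionTime" type="tml:retentionTimeType"
                  maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="peptideType">
    <xs:sequence>
      <xs:element name="cvParam" type="tml:cvParamType" minOccurs="0"
                  maxOccurs="unbounded"/>
      <xs:element name="RetentionTimeList" type="tml:retentionTimeListType"
                  minOccurs="0"/>
    </xs:sequence>
    <xs:attribute name="id" type="xs:string" use="required"/>
    <xs:attribute name="sequence" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="ionType">
    <xs:sequence>
      <xs:element name="cvParam" type="tml:cvParamType" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="transitionType">
    <xs:sequence>
      <xs:element name="Precursor" type="tml:ionType"/>
      <xs:element name="Product" type="tml:ionType"/>
      <xs:element name="cvParam" type="tml:cvParamType" minOccurs="0"
                  maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attribute name="id" type="xs:string" use="required"/>
    <xs:attribute name="peptideRef" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:element name="TraML">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="cvList">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="cv" type="tml:cvType" maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="CompoundList" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="Peptide" type="tml:peptideType" minOccurs="0"
                          maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="TransitionList">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="Transition" type="tml:transitionType"
                          minOccurs="0" maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="version" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
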